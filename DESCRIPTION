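Package: girefine
Title: Network-Refined Genetic Interactions from Cancer Dependency Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes sensitive and resistant genetic interactions (GIs)
    between recurrently mutated genes and loss-of-function screened genes in
    cancer cell-line panels. Depletion scores from CRISPR or shRNA screens are
    compared between mutant and wild-type cell lines by Welch or Student
    t-tests with Benjamini-Hochberg false-discovery-rate control, optionally
    masking depletion scores of nonexpressed genes. Candidate synthetic
    partners are then refined on KEGG-style directed or protein-protein
    interaction networks by requiring another partner of the same mutated gene
    within network distance one or two, and the retained partners are exported
    as synthetic partner networks (SPNs). Includes precision/recall evaluation
    against reference synthetic-lethality pair sets and a seeded synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
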