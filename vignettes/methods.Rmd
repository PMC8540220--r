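---
title: "Characterizing and refining cancer genetic interactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing and refining cancer genetic interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(girefine)
```

## The model

A loss-of-function screen measures, for each screened gene $K$ and cell
line $c$, a depletion score: low values mean cells die when $K$ is lost,
high values mean loss of $K$ favors proliferation. Given a mutation profile
over the same cell-line panel, a genetic interaction (GI) between a
recurrently mutated gene $Q$ and a screened gene $K$ is a differential
essentiality: the depletion scores of $K$ differ between cells carrying a
functional mutation in $Q$ (case) and the remaining cells (control).

`girefine` tests every (Q, K) pair with a two-sided two-sample $t$-test and
labels the pair *sensitive* when the case mean is lower and *resistant*
when it is higher. All p-values obtained in one screening form a single
Benjamini–Hochberg family — the direction is a post-hoc sign label, not a
separate family — and pairs with adjusted FDR below the threshold (default
0.2) are reported.

Two constraints reduce false positives:

* **Exclusion procedure.** If the expression value matched to a depletion
  entry (same gene, same cell line, joined on the cell-line primary key) is
  zero, the depletion entry is masked before testing: perturbing a
  nonexpressed gene cannot affect the cell, so any signal there is
  technical. Entries with no matching expression record are used as they
  are.
* **Refining process (RP).** The synthetic partners (SPs) of a mutated
  gene should be mutually close on a molecular network. After mapping the
  SPs of each mutated gene onto the network, an SP is retained iff another
  SP of the same mutated gene lies within distance $k$ ($k = 1$ or $2$).
  The retained SPs, their induced edges, and — at $k = 2$ — the non-SP
  genes realizing length-2 paths between them form the synthetic partner
  network (SPN).

## Assumptions

* Depletion scores within each group are modeled as exchangeable real
  values; the $t$-test is used descriptively, with no claim that scores are
  exactly Gaussian. Welch's unequal-variance form is the default because
  mutant groups are typically an order of magnitude smaller than wild-type
  groups.
* Functional mutation is binary: one deleterious variant event (from a
  twelve-class vocabulary of damaging classifications: frame shifts,
  nonsense, nonstop, splice site, start/stop-codon gains and losses,
  in-frame deletion, de novo start out of frame, missense) makes a gene
  mutated in that cell line. No variant-level effect prediction is
  attempted.
* Network proximity is meaningful for GI plausibility; edge direction on
  pathway-derived networks is treated symmetrically by default (see below).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fdr_threshold` | 0.2 | BH-adjusted FDR below which a pair is reported |
| `min_group_size` | 3 | smallest case/control group tested (a $t$-test is undefined below 2, unstable at 2); skipped pairs leave the BH family |
| `t_variant` | `"welch"` | `"student"` pools variances |
| `expression_zero_epsilon` | 0 | expression at or below this counts as nonexpressed; raise slightly to absorb TPM noise |
| recurrence `theta` | 0.03 | a gene is recurrently mutated when its frequency strictly exceeds this ("more than 3%" read literally; `strict = FALSE` gives $\ge$) |
| RP `k` | 2 and 1 | network distance defining SP adjacency |
| `direction_mode` | `"either"` | directed networks: a directed path in either orientation confers proximity |
| `min_sps` | 2 | mutated genes with fewer mapped SPs are skipped: the RP needs a second SP to ask about |

## Design choices made where the design was open

* **$t$-test flavor and group-size floor.** Neither is dictated by the
  procedure definition; Welch with a floor of 3 per group is the default,
  both are configurable. Skipped (degenerate) pairs are excluded from the
  BH family size so they do not dilute the adjustment.
* **Direction on directed networks.** Adjacency of SPs is a symmetric
  idea, so the default `"either"` accepts a directed path in either
  orientation; `"ignore"` (fully undirected) and `"forward"` are available.
  On undirected PPI-style networks the modes coincide.
* **Single-pass refinement.** The RP filters against the *initial* SP set:
  removing one SP never cascades into removing another whose only near
  neighbor it was. Under the symmetric default this distinction is
  invisible (proximity is mutual, so a retained SP's witness is itself
  retained); it matters only in `"forward"` mode, and a `fixed_point`
  switch selects the iterative variant.
* **The mutated gene as its own SP.** A self-interaction (Q among its own
  partners, e.g. an oncogene addiction) participates as an ordinary SP
  node when it maps to the network; its mere presence as a network node
  never rescues other SPs unless it is itself an SP. Self-pairs are
  excluded from reference-set evaluation, which contains no self-pairs.
* **Unordered pair matching in evaluation.** Predicted GIs are ordered
  (mutated, target) but synthetic-lethal reference pairs are symmetric;
  matching is on unordered pairs by default, ordered by flag. Only
  sensitive GIs are evaluated, matching the synthetic-lethal semantics of
  the reference sets.
* **Missing values.** Per-entry missingness is kept (tests use
  pairwise-complete values); blank, `NA` and `NaN` tokens map to the
  missing marker, while an expression value of exactly zero is data
  (nonexpressed), never missing.
* **Label handling.** Gene labels like `"BRAF (673)"` are reduced to the
  bare symbol, since the mutation, screen, expression and network gene
  spaces share only symbols; matrix orientation is auto-detected from
  which axis carries cell-ID-prefixed labels, and ambiguity is an error
  rather than a guess.

## Numerical notes

* The row-wise Welch/Student statistic is computed vectorized over all
  screened genes for one mutated gene at a time; it agrees with
  `stats::t.test` to machine precision (asserted in the test suite).
* A pair with zero variance in both groups and equal means is skipped; with
  unequal means its statistic diverges and the p-value is 0.
* BH adjustment is `stats::p.adjust(method = "BH")` with an explicit family
  size, so a screening split across calls can still be adjusted as one
  family.
* Ties and ordering: output tables are sorted (mutated gene, then target
  gene); SPN nodes and edges are emitted in deterministic sorted order;
  undirected edges are stored with endpoints in canonical order.

## The synthetic-data generator

`synth_config()` describes a desk-scale screen whose defaults are the
package's study conditions: 200 cell lines, 10 mutated genes at mutation
frequency 0.1 (forced above the 3% recurrence threshold), 500 screened
genes (5,000 tested pairs), Gaussian depletion noise with standard
deviation 0.2, planted mean shifts of 1.0 in mutant cells for 20 true
sensitive interactions, 10 decoy interactions, a 16% nonexpressed fraction
(the approximate zero fraction of real expression profiles), and 50 noise
reference pairs. Each mutated gene's true partners form a clique in the
emitted network; decoys receive a real depletion shift (the screen should
find them) but live in private network components, at least three steps
from every other partner (the refinement should remove them). Optional
confound pairs reproduce the expression-artifact pattern: the partner's
depletion shift lies entirely in mutant cells where the partner is
nonexpressed, so the exclusion procedure erases the signal.

What the generator deliberately does **not** emulate: the empirical
(heavy-tailed, gene-correlated) distribution of real depletion scores,
gene–gene coexpression structure, copy-number confounding, or realistic
network topology (scale-free hubs). Passing tests on this generator
demonstrate the pipeline's correctness and its qualitative behavior
(precision gains from refinement, recall monotonicity, confound removal),
not performance guarantees on real screens.

A genuine limitation surfaced by the generator: because every screened
gene is tested against every mutated gene, a partner planted for one
mutated gene is a variance-inflated mixture — not a clean null — when
tested against the others, and the BH step-up at FDR 0.2 itself admits
roughly 20% false discoveries among the reported pairs. Per-run false
calls therefore sit well above zero (the acceptance checks document the
measured rates); they are overwhelmingly network-isolated and removed by
the refining process, which is precisely the pipeline's argument.

## Problem sizes

The test suite and the acceptance script run the generator at the default
conditions above (5,000 pairs per screen) across 10–20 seeds per property,
and validate the network primitives against brute-force oracles on random
graphs of up to 50 nodes; the whole suite completes in well under a minute
on a single core. These sizes were chosen to make every property cheap to
re-verify while keeping all group-size and threshold regimes of the full
method exercised.

## Known limitations

* Matching across data sources is by gene symbol only; no Entrez/Ensembl
  reconciliation.
* The screen assumes the mutation profile covers every profiled cell line
  (a line absent from the variant table is absent from the analysis, not
  assumed wild type).
* The RP asks only for *one* near partner; it does not score connectivity
  strength or penalize hub-driven adjacency, which on dense PPI networks
  makes distance-2 refinement weak (most SPs survive RP2 when hubs are
  present).
* Cancer-type-specific analysis is out of scope; all cell lines are pooled.
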