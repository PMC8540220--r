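# End-to-end orchestration: screen -> refine (k = 2, 1) -> SPN export ->
# (optional) evaluation, with a run manifest. Stage outputs are files so
# each stage is independently re-runnable and inspectable.

#' Run the full GI characterization and refinement pipeline
#'
#' Reads the inputs named in the configuration, characterizes GIs
#' ([characterize_gis()]), refines them on the network at distances 2 and 1
#' ([refine_gis()]), exports per-mutated-gene SPNs, optionally evaluates the
#' sensitive GIs against a reference pair set, and writes a JSON run
#' manifest with per-stage counts and input digests.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognized keys:
#' \describe{
#'   \item{inputs}{`depletion`, `variants` (paths; required), `expression`,
#'     `network`, `reference` (paths; optional), `network_directed` (flag,
#'     default `FALSE`), plus optional `depletion_orientation` /
#'     `expression_orientation` overrides.}
#'   \item{screen}{`fdr_threshold`, `min_group_size`, `t_variant`,
#'     `exclusion`, `expression_zero_epsilon` (see [gi_test_config()]),
#'     `recurrence_threshold`, `recurrence_strict`.}
#'   \item{refine}{`distances` (default `c(2, 1)`), `direction_mode`,
#'     `min_sps`, `fixed_point`, `export_format`.}
#' }
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the stage GI tables, refinements, metrics
#'   (when a reference was given) and the manifest.
#' @export
run_gi_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inp <- config$inputs %||% stop("config lacks an 'inputs' section",
                                 call. = FALSE)
  for (req in c("depletion", "variants")) {
    if (is.null(inp[[req]])) {
      stop("config inputs lack '", req, "'", call. = FALSE)
    }
  }
  want_refine <- !is.null(inp$network)
  paths <- unlist(inp[names(inp) %in% c("depletion", "variants", "expression",
                                        "network", "reference")])
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  scr <- config$screen %||% list()
  test_cfg <- gi_test_config(
    fdr_threshold = scr$fdr_threshold %||% 0.2,
    min_group_size = scr$min_group_size %||% 3L,
    t_variant = scr$t_variant %||% "welch",
    exclusion = scr$exclusion %||% TRUE,
    expression_zero_epsilon = scr$expression_zero_epsilon %||% 0
  )
  rf <- config$refine %||% list()

  manifest <- list(config = config,
                   inputs = lapply(paths, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))),
                   stages = list(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  stage <- function(name, counts) {
    manifest$stages[[name]] <<- c(counts,
                                  at = format(Sys.time(),
                                              "%Y-%m-%dT%H:%M:%S%z"))
  }

  variants <- read_variant_table(inp$variants)
  mutations <- call_functional_mutations(variants)
  recurrent <- select_recurrent_genes(
    mutations, theta = scr$recurrence_threshold %||% 0.03,
    strict = scr$recurrence_strict %||% TRUE)
  stage("mutation_calling",
        list(n_variant_records = nrow(variants),
             n_mutated_genes = nrow(mutations),
             n_recurrent_genes = length(recurrent)))

  depletion <- read_score_matrix(inp$depletion, role = "depletion",
                                 orientation = inp$depletion_orientation %||%
                                   "auto")
  expression <- if (!is.null(inp$expression)) {
    read_score_matrix(inp$expression, role = "expression",
                      orientation = inp$expression_orientation %||% "auto")
  }
  gi <- characterize_gis(depletion, mutations, recurrent,
                         expression = expression, config = test_cfg)
  write_gi_table(gi, file.path(out_dir, "gi_screen.tsv"))
  stage("screen", list(n_tests = attr(gi, "n_tests"),
                       n_skipped = attr(gi, "n_skipped"),
                       n_gis = nrow(gi),
                       n_sensitive = sum(gi$direction == "sensitive"),
                       n_resistant = sum(gi$direction == "resistant")))

  tables <- list(screen = gi)
  refined <- NULL
  if (want_refine) {
    network <- load_network(inp$network,
                            directed = isTRUE(inp$network_directed))
    refined <- refine_gis(gi, network,
                          distances = rf$distances %||% c(2L, 1L),
                          direction_mode = rf$direction_mode %||% "either",
                          min_sps = rf$min_sps %||% 2L,
                          fixed_point = isTRUE(rf$fixed_point))
    for (nm in names(refined$tables)) {
      write_gi_table(refined$tables[[nm]],
                     file.path(out_dir, paste0("gi_", tolower(nm), ".tsv")))
    }
    spn_dir <- file.path(out_dir, "spn")
    dir.create(spn_dir, showWarnings = FALSE)
    fmt <- rf$export_format %||% "tsv"
    ext <- c(tsv = "tsv", sif = "sif", graphml = "graphml")[[fmt]]
    for (rp in names(refined$refinements)) {
      k <- as.integer(sub("RP", "", rp))
      for (q in names(refined$refinements[[rp]])) {
        spn <- build_spn(refined$refinements[[rp]][[q]], network, gi, k,
                         direction_mode = rf$direction_mode %||% "either")
        export_spn(spn, file.path(spn_dir,
                                  sprintf("%s_spn%d.%s", q, k, ext)),
                   format = fmt)
      }
    }
    counts <- lapply(refined$tables, nrow)
    stage("refine", c(list(n_mutated_mapped = length(refined$sps),
                           n_skipped_q = sum(vapply(refined$sps, `[[`,
                                                    TRUE, "skipped"))),
                      stats::setNames(counts,
                                      paste0("n_gis_", tolower(names(counts))))))
    tables <- c(tables, refined$tables)
  }

  metrics <- NULL
  if (!is.null(inp$reference)) {
    reference <- load_reference_pairs(inp$reference)
    eval_tables <- if (want_refine) refined$tables else list(screen = gi)
    metrics <- stage_comparison(eval_tables, reference)
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage("evaluate", list(n_reference = length(reference)))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(list(tables = tables, refinements = refined$refinements,
                 metrics = metrics, manifest = manifest))
}
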