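# Evaluation of predicted sensitive GIs against reference synthetic-lethal
# pair sets (SynLethDB/MiSL-style two-column lists) with recall/precision.

canonical_pairs <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste(lo, hi, sep = "\r")
}

#' Load a reference synthetic-lethality pair set
#'
#' Two-column TSV of gene symbols. Pairs are unordered: `(A, B)` and
#' `(B, A)` collapse to one pair; self-pairs are dropped (with a message).
#'
#' @param path two-column TSV (optional header tolerated).
#' @return character vector of canonical pair keys with attribute `pairs`, a
#'   two-column data.frame of the deduplicated pairs.
#' @export
load_reference_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty reference file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed pair at line ", bad[1L], " of ", path, call. = FALSE)
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  if (identical(tolower(c(a[1L], b[1L])), c("gene1", "gene2")) ||
      identical(tolower(c(a[1L], b[1L])), c("gene_a", "gene_b"))) {
    a <- a[-1L]
    b <- b[-1L]
  }
  self <- a == b
  if (any(self)) {
    message("dropped ", sum(self), " self-pair(s) from reference set")
    a <- a[!self]
    b <- b[!self]
  }
  keys <- unique(canonical_pairs(a, b))
  lo <- vapply(strsplit(keys, "\r", fixed = TRUE), `[[`, "", 1L)
  hi <- vapply(strsplit(keys, "\r", fixed = TRUE), `[[`, "", 2L)
  structure(keys, pairs = data.frame(gene1 = lo, gene2 = hi,
                                     stringsAsFactors = FALSE))
}

#' Reference pair keys from a data.frame of pairs
#'
#' Programmatic counterpart of [load_reference_pairs()], used by the
#' synthetic-data generator and tests.
#'
#' @param pairs data.frame whose first two columns are gene symbols.
#' @return canonical pair keys (self-pairs dropped, deduplicated).
#' @export
reference_pairs <- function(pairs) {
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  keep <- a != b
  unique(canonical_pairs(a[keep], b[keep]))
}

#' Score predicted GIs against a reference pair set
#'
#' Reference sets contain synthetic lethal interactions, so only GIs in the
#' sensitive direction are compared by default; matching is on unordered
#' pairs, and self-GIs (mutated gene equal to target) are excluded since
#' reference sets carry no self-pairs.
#'
#' @param gi_table GI table.
#' @param reference canonical pair keys from [load_reference_pairs()] or
#'   [reference_pairs()].
#' @param stage_label label recorded in the output row.
#' @param sensitive_only compare only sensitive GIs (default).
#' @param ordered match ordered (mutated, target) pairs against reference
#'   rows as given instead of unordered pairs.
#' @return one-row data.frame: `stage`, `n_predicted`, `n_reference`,
#'   `n_hits`, `precision` (`NA` when nothing is predicted), `recall`.
#' @export
evaluate_gis <- function(gi_table, reference, stage_label = "GI",
                         sensitive_only = TRUE, ordered = FALSE) {
  if (length(reference) == 0L) stop("empty reference set", call. = FALSE)
  tab <- as.data.frame(gi_table)
  if (sensitive_only) tab <- tab[tab$direction == "sensitive", , drop = FALSE]
  tab <- tab[tab$mutated_gene != tab$target_gene, , drop = FALSE]
  predicted <- if (ordered) {
    unique(paste(tab$mutated_gene, tab$target_gene, sep = "\r"))
  } else {
    unique(canonical_pairs(tab$mutated_gene, tab$target_gene))
  }
  n_hits <- sum(predicted %in% reference)
  data.frame(
    stage = stage_label,
    n_predicted = length(predicted),
    n_reference = length(reference),
    n_hits = n_hits,
    precision = if (length(predicted)) n_hits / length(predicted) else NA_real_,
    recall = n_hits / length(reference),
    stringsAsFactors = FALSE
  )
}

#' Compare evaluation metrics across refinement stages
#'
#' Takes the stage GI tables (typically `INIT`, `RP2`, `RP1` from
#' [refine_gis()]), verifies that each later stage's predicted pair set is
#' nested in the previous one, and returns one metrics row per stage. Because
#' the reference is fixed and the stages are nested, recall is necessarily
#' non-increasing along the stage order; a violation signals an upstream bug
#' and raises an error.
#'
#' @param gi_tables named list of GI tables, ordered from least to most
#'   refined (e.g. `list(INIT = ..., RP2 = ..., RP1 = ...)`).
#' @param reference canonical pair keys.
#' @param sensitive_only see [evaluate_gis()].
#' @return data.frame of per-stage metrics in the given order.
#' @export
stage_comparison <- function(gi_tables, reference, sensitive_only = TRUE) {
  stopifnot(is.list(gi_tables), length(gi_tables) >= 1L)
  labels <- names(gi_tables) %||% paste0("stage", seq_along(gi_tables))
  pair_sets <- lapply(gi_tables, function(tab) {
    df <- as.data.frame(tab)
    if (sensitive_only) df <- df[df$direction == "sensitive", , drop = FALSE]
    df <- df[df$mutated_gene != df$target_gene, , drop = FALSE]
    unique(canonical_pairs(df$mutated_gene, df$target_gene))
  })
  for (i in seq_along(pair_sets)[-1L]) {
    if (!all(pair_sets[[i]] %in% pair_sets[[i - 1L]])) {
      stop("stage '", labels[i], "' is not nested in stage '",
           labels[i - 1L], "'", call. = FALSE)
    }
  }
  rows <- mapply(function(tab, lab) {
    evaluate_gis(tab, reference, stage_label = lab,
                 sensitive_only = sensitive_only)
  }, gi_tables, labels, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.unsorted(rev(out$recall))) {
    stop("recall increased along nested stages; upstream nesting is broken",
         call. = FALSE)
  }
  out
}
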