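# Functional-mutation calling: variant events -> binary gene x cell matrix,
# and selection of recurrently mutated genes.

#' The default deleterious variant-classification vocabulary
#'
#' Twelve variant classes are treated as deleterious: de novo start out of
#' frame, frame-shift deletion/insertion, in-frame deletion, nonsense,
#' nonstop, splice site, start-codon deletion/insertion, stop-codon
#' deletion/insertion, and missense. Comparison against the vocabulary is
#' case-insensitive after collapsing space/underscore separators, so MAF-style
#' spellings such as `"Missense_Mutation"` or `"Splice_Site"` match.
#'
#' @param extra additional classification strings to treat as deleterious.
#' @return normalized character vector of deleterious classes.
#' @export
deleterious_vocabulary <- function(extra = character(0)) {
  base <- c(
    "de_novo_start_out_of_frame",
    "frame_shift_del", "frame_shift_ins",
    "in_frame_del",
    "nonsense_mutation", "nonstop_mutation",
    "splice_site",
    "start_codon_del", "start_codon_ins",
    "stop_codon_del", "stop_codon_ins",
    "missense_mutation"
  )
  unique(c(base, normalize_classification(extra)))
}

normalize_classification <- function(x) {
  gsub("[ _]+", "_", tolower(trimws(x)))
}

#' Call functional mutations per gene and cell line
#'
#' A gene is functionally mutated in a cell line if at least one of its
#' variant events there has a deleterious classification. Unrecognized
#' classifications count as non-deleterious (each distinct label is reported
#' once via `message()`).
#'
#' @param variant_table from [read_variant_table()].
#' @param vocabulary deleterious classes, see [deleterious_vocabulary()].
#' @param cell_universe cell IDs forming the matrix columns; cells without
#'   any variant record get all-zero columns. Defaults to the cells observed
#'   in `variant_table`.
#' @return binary genes x cells matrix with a `"counts"` attribute holding
#'   the number of deleterious events behind each 1 entry.
#' @export
call_functional_mutations <- function(variant_table,
                                      vocabulary = deleterious_vocabulary(),
                                      cell_universe = NULL) {
  if (is.null(cell_universe)) cell_universe <- sort(unique(variant_table$cell_id))
  cell_universe <- unique(cell_universe)
  if (length(cell_universe) == 0L) stop("empty cell universe", call. = FALSE)

  cls <- normalize_classification(variant_table$variant_classification)
  deleterious <- cls %in% vocabulary
  unknown <- setdiff(unique(cls[!deleterious]), vocabulary)
  if (length(unknown)) {
    message("treating ", length(unknown),
            " variant classification(s) as non-deleterious: ",
            paste(sort(unknown), collapse = ", "))
  }
  hits <- variant_table[deleterious & variant_table$cell_id %in% cell_universe, ,
                        drop = FALSE]
  genes <- sort(unique(hits$gene))
  mat <- matrix(0L, nrow = length(genes), ncol = length(cell_universe),
                dimnames = list(genes, cell_universe))
  counts <- mat
  if (nrow(hits)) {
    tab <- table(factor(hits$gene, levels = genes),
                 factor(hits$cell_id, levels = cell_universe))
    counts <- matrix(as.integer(tab), nrow = length(genes),
                     dimnames = dimnames(mat))
    mat[counts > 0L] <- 1L
  }
  attr(mat, "counts") <- counts
  mat
}

#' Select recurrently mutated genes
#'
#' A gene passes when its mutation frequency across the cell universe exceeds
#' the threshold `theta` (default 3%). The comparison is strict (`>`) by
#' default, reading "more than" literally; `strict = FALSE` switches to `>=`.
#'
#' @param mutation_matrix binary matrix from [call_functional_mutations()].
#' @param theta recurrence threshold as a fraction of cell lines.
#' @param strict use strict inequality (default) or `>=`.
#' @return character vector of recurrent gene symbols, with attributes
#'   `theta` and `n_cells` (the denominator).
#' @export
select_recurrent_genes <- function(mutation_matrix, theta = 0.03,
                                   strict = TRUE) {
  stopifnot(theta >= 0, theta < 1)
  n_cells <- ncol(mutation_matrix)
  if (n_cells == 0L) stop("mutation matrix has no cell lines", call. = FALSE)
  freq <- rowSums(mutation_matrix) / n_cells
  keep <- if (strict) freq > theta else freq >= theta
  structure(rownames(mutation_matrix)[keep], theta = theta, n_cells = n_cells)
}
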