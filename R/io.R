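# Readers and writers for the tabular inputs of the screen, in
# DepMap-compatible dialects, and for the pipeline's own GI tables.

#' Describe the column layout of a variant (mutation) file
#'
#' @param cell_col column holding the cell-line primary key (DepMap ID).
#' @param gene_col column holding the HUGO gene symbol (a trailing
#'   `"(EntrezID)"` token is stripped).
#' @param class_col column holding the variant classification string.
#' @return a named list used as `dialect` by [read_variant_table()].
#' @export
variant_dialect <- function(cell_col = "DepMap_ID",
                            gene_col = "Hugo_Symbol",
                            class_col = "Variant_Classification") {
  list(cell_col = cell_col, gene_col = gene_col, class_col = class_col)
}

#' Read a per-event variant table
#'
#' One row per mutation event, CCLE/DepMap `CCLE_mutation.csv` style. The
#' variant classification is retained verbatim; deciding which classes are
#' deleterious happens downstream in [call_functional_mutations()].
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line).
#' @param dialect column mapping from [variant_dialect()].
#' @return a `data.frame` with columns `cell_id`, `gene`,
#'   `variant_classification`, row order preserved.
#' @export
read_variant_table <- function(path, dialect = variant_dialect()) {
  delim <- sniff_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  for (col in unlist(dialect)) {
    if (!col %in% names(df)) {
      stop("variant file ", path, " lacks required column '", col, "'",
           call. = FALSE)
    }
  }
  if (nrow(df) == 0L) stop("variant file has no records: ", path, call. = FALSE)
  out <- data.frame(
    cell_id = df[[dialect$cell_col]],
    gene = strip_gene_suffix(df[[dialect$gene_col]]),
    variant_classification = df[[dialect$class_col]],
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$cell_id)) || any(!nzchar(out$gene))) {
    stop("variant records with empty cell ID or gene symbol", call. = FALSE)
  }
  out
}

#' Construct a score matrix (depletion or expression role)
#'
#' The canonical layout is genes as rows, cell lines as columns, with `NA`
#' marking missing entries (distinct from zero: a zero expression value means
#' the gene is nonexpressed in that cell line, not unmeasured).
#'
#' @param values numeric matrix, genes x cells, with dimnames.
#' @param role `"depletion"` (loss-of-function viability effect) or
#'   `"expression"` (log2(TPM+1)-scale, non-negative).
#' @return the matrix with a `role` attribute, validated.
#' @export
score_matrix <- function(values, role = c("depletion", "expression")) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("score matrix body must be a numeric matrix", call. = FALSE)
  }
  genes <- rownames(values)
  cells <- colnames(values)
  if (is.null(genes) || is.null(cells)) {
    stop("score matrix needs gene row names and cell column names",
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene symbols in score matrix: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cells)) {
    stop("duplicate cell IDs in score matrix", call. = FALSE)
  }
  if (role == "expression") {
    neg <- values[is.finite(values) & values < 0]
    if (length(neg)) {
      stop("expression matrix contains negative values", call. = FALSE)
    }
  }
  attr(values, "role") <- role
  values
}

#' Read a score matrix in either on-disk orientation
#'
#' DepMap publishes depletion matrices in both orientations
#' (`Achilles_gene_effect.csv` is cells x genes, `D2_combined_gene_dep_scores`
#' is genes x cells). `orientation = "auto"` detects the cell axis as the
#' label set in which at least half the labels carry the cell-ID prefix
#' (default `"ACH-"`); when both or neither axis qualifies, an explicit
#' orientation is demanded.
#'
#' @param path CSV/TSV file with one label row and one label column.
#' @param role passed to [score_matrix()].
#' @param orientation `"auto"`, `"genes_by_cells"` or `"cells_by_genes"`.
#' @param cell_prefix prefix identifying cell-ID labels for auto-detection.
#' @param na_tokens strings mapped to the missing marker.
#' @return a genes x cells [score_matrix()].
#' @export
read_score_matrix <- function(path, role = c("depletion", "expression"),
                              orientation = c("auto", "genes_by_cells",
                                              "cells_by_genes"),
                              cell_prefix = "ACH-",
                              na_tokens = c("", "NA", "NaN")) {
  role <- match.arg(role)
  orientation <- match.arg(orientation)
  delim <- sniff_delim(path)
  raw <- utils::read.table(path, sep = delim, header = TRUE, row.names = 1L,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop("score matrix file has no data body: ", path, call. = FALSE)
  }
  chr <- as.matrix(raw)
  chr[chr %in% na_tokens] <- NA_character_
  num <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(num) & !is.na(chr))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(chr))
    stop("non-numeric value '", chr[bad[1L]], "' at row '",
         rownames(chr)[idx[1L]], "', column '", colnames(chr)[idx[2L]],
         "' of ", path, call. = FALSE)
  }
  mat <- matrix(num, nrow = nrow(chr), dimnames = dimnames(chr))

  if (orientation == "auto") {
    row_frac <- mean(startsWith(rownames(mat), cell_prefix))
    col_frac <- mean(startsWith(colnames(mat), cell_prefix))
    if (row_frac >= 0.5 && col_frac < 0.5) {
      orientation <- "cells_by_genes"
    } else if (col_frac >= 0.5 && row_frac < 0.5) {
      orientation <- "genes_by_cells"
    } else {
      stop("cannot auto-detect orientation of ", path,
           " (cell-ID prefix '", cell_prefix, "' matches ",
           round(100 * row_frac), "% of rows and ", round(100 * col_frac),
           "% of columns); pass orientation explicitly", call. = FALSE)
    }
  }
  if (orientation == "cells_by_genes") mat <- t(mat)

  genes <- strip_gene_suffix(rownames(mat))
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene symbols after suffix stripping in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  rownames(mat) <- genes
  score_matrix(mat, role)
}

#' Intersect cell-line IDs across screen inputs
#'
#' Cell lines are joined on their DepMap-style primary key. The alignment is
#' the sorted intersection across all supplied sources; matrices contribute
#' their column names, variant tables their `cell_id` column.
#'
#' @param ... two or more score matrices, mutation matrices, or variant
#'   tables.
#' @return sorted character vector of shared cell IDs.
#' @export
align_cells <- function(...) {
  sources <- list(...)
  if (length(sources) < 2L) stop("need at least two sources", call. = FALSE)
  ids <- lapply(sources, function(s) {
    if (is.matrix(s)) colnames(s)
    else if (is.data.frame(s) && "cell_id" %in% names(s)) unique(s$cell_id)
    else stop("cannot extract cell IDs from a ", class(s)[1L], call. = FALSE)
  })
  shared <- Reduce(intersect, ids)
  if (length(shared) == 0L) {
    stop("no cell lines shared across the supplied sources", call. = FALSE)
  }
  sort(shared)
}

gi_table_columns <- c("mutated_gene", "target_gene", "direction", "t_stat",
                      "p_value", "fdr", "n_case", "n_control",
                      "n_masked_case", "n_masked_control")

new_gi_table <- function(records, n_tests, n_skipped = 0L, config = NULL) {
  stopifnot(all(gi_table_columns %in% names(records)))
  records <- records[, gi_table_columns, drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            class = c("gi_table", "data.frame"),
            n_tests = as.integer(n_tests),
            n_skipped = as.integer(n_skipped),
            config = config)
}

#' @export
as.data.frame.gi_table <- function(x, ...) {
  attr(x, "n_tests") <- NULL
  attr(x, "n_skipped") <- NULL
  attr(x, "config") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.gi_table <- function(x, ...) {
  cat("GI table: ", nrow(x), " interactions (",
      sum(x$direction == "sensitive"), " sensitive, ",
      sum(x$direction == "resistant"), " resistant) from ",
      attr(x, "n_tests") %||% NA_integer_, " tests\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}

#' Write / read a GI table as TSV
#'
#' Serializes all record fields plus the size of the test family (needed to
#' interpret the BH-adjusted FDR values) losslessly; floats survive the round
#' trip to at least 12 significant digits.
#'
#' @param gi_table a GI table from [characterize_gis()].
#' @param path output TSV path.
#' @return `write_gi_table()` returns `path` invisibly; `read_gi_table()`
#'   returns the GI table.
#' @export
write_gi_table <- function(gi_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gi_table n_tests=%d n_skipped=%d",
                     attr(gi_table, "n_tests") %||% nrow(gi_table),
                     attr(gi_table, "n_skipped") %||% 0L), con)
  out <- as.data.frame(gi_table)
  for (col in c("t_stat", "p_value", "fdr")) out[[col]] <- format_num(out[[col]])
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gi_table
#' @export
read_gi_table <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  meta <- c(n_tests = NA_integer_, n_skipped = 0L)
  skip <- 0L
  if (length(first) && startsWith(first, "#")) {
    skip <- 1L
    for (key in names(meta)) {
      m <- regmatches(first, regexec(paste0(key, "=([0-9]+)"), first))[[1L]]
      if (length(m) == 2L) meta[[key]] <- as.integer(m[2L])
    }
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(mutated_gene = "character",
                                         target_gene = "character",
                                         direction = "character"))
  if (nrow(df) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(gi_table_columns)), gi_table_columns))
    num_cols <- setdiff(gi_table_columns,
                        c("mutated_gene", "target_gene", "direction"))
    for (col in num_cols) df[[col]] <- numeric(0)
  }
  if (is.na(meta[["n_tests"]])) meta[["n_tests"]] <- nrow(df)
  new_gi_table(df, n_tests = meta[["n_tests"]], n_skipped = meta[["n_skipped"]])
}
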