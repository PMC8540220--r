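# Differential-essentiality screen: expression-masked two-sample t-tests of
# depletion scores between mutant and wild-type cell lines, with global
# Benjamini-Hochberg FDR control.

#' Screen configuration
#'
#' @param fdr_threshold report interactions with BH-adjusted FDR below this
#'   (default 0.2).
#' @param min_group_size minimum non-missing depletion values required in each
#'   of the mutant and wild-type groups for a pair to be tested (default 3; a
#'   t-test is undefined below 2 and unstable at 2).
#' @param t_variant `"welch"` (unequal variances; mutant and wild-type group
#'   sizes typically differ wildly) or `"student"` (pooled variance).
#' @param exclusion apply the nonexpression exclusion procedure
#'   ([mask_nonexpressed()]) before testing.
#' @param expression_zero_epsilon expression values at or below this count as
#'   nonexpressed (default 0: exact-zero semantics; raise slightly to absorb
#'   TPM noise).
#' @return a `gi_test_config` list.
#' @export
gi_test_config <- function(fdr_threshold = 0.2, min_group_size = 3L,
                           t_variant = c("welch", "student"),
                           exclusion = TRUE,
                           expression_zero_epsilon = 0) {
  t_variant <- match.arg(t_variant)
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            min_group_size >= 2L, expression_zero_epsilon >= 0)
  structure(list(fdr_threshold = fdr_threshold,
                 min_group_size = as.integer(min_group_size),
                 t_variant = t_variant,
                 exclusion = isTRUE(exclusion),
                 expression_zero_epsilon = expression_zero_epsilon),
            class = "gi_test_config")
}

#' Mask depletion scores of nonexpressed genes
#'
#' Loss of a gene that is not expressed cannot affect the cell, so a
#' non-trivial depletion score there reflects a technical artifact (e.g. the
#' CRISPR DNA-damage response or shRNA off-target effects). The entry
#' `(gene, cell)` of the depletion matrix becomes missing when the expression
#' matrix has a value for that gene and cell and it is at or below `epsilon`.
#' Genes or cells absent from the expression matrix are left untouched — the
#' depletion score is used as it is.
#'
#' @param depletion genes x cells depletion [score_matrix()].
#' @param expression genes x cells expression [score_matrix()]
#'   (log2(TPM+1)-scale; zero means nonexpressed).
#' @param epsilon nonexpression cutoff (default 0).
#' @return the depletion matrix with masked entries set to `NA`.
#' @export
mask_nonexpressed <- function(depletion, expression, epsilon = 0) {
  genes <- intersect(rownames(depletion), rownames(expression))
  cells <- intersect(colnames(depletion), colnames(expression))
  if (length(genes) && length(cells)) {
    expr <- expression[genes, cells, drop = FALSE]
    mask <- !is.na(expr) & expr <= epsilon
    sub <- depletion[genes, cells, drop = FALSE]
    sub[mask] <- NA_real_
    depletion[genes, cells] <- sub
  }
  depletion
}

# Row-wise two-sample t statistics of a genes x cells matrix split by a
# logical case mask over the columns. Returns one row per gene with group
# sizes, t, two-sided p, and the sign-derived direction; rows failing the
# group-size rule (or degenerate zero-variance/equal-means rows) are flagged
# `skip`. Vectorized: at recurrent-gene x screened-gene scale the screen
# performs millions of tests.
row_t_test <- function(values, case, t_variant = "welch", min_group_size = 3L) {
  stopifnot(length(case) == ncol(values))
  X <- values[, case, drop = FALSE]
  Y <- values[, !case, drop = FALSE]
  gs <- function(M) {
    n <- rowSums(!is.na(M))
    m <- rowSums(M, na.rm = TRUE) / n
    v <- rowSums((M - m)^2, na.rm = TRUE) / (n - 1L)
    list(n = n, m = m, v = v)
  }
  a <- gs(X)
  b <- gs(Y)
  skip <- a$n < min_group_size | b$n < min_group_size
  degenerate <- !skip & a$v == 0 & b$v == 0 & a$m == b$m
  skip <- skip | degenerate

  diff <- a$m - b$m
  if (t_variant == "welch") {
    se2 <- a$v / a$n + b$v / b$n
    df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1L) + (b$v / b$n)^2 / (b$n - 1L))
  } else {
    sp2 <- ((a$n - 1L) * a$v + (b$n - 1L) * b$v) / (a$n + b$n - 2L)
    se2 <- sp2 * (1 / a$n + 1 / b$n)
    df <- a$n + b$n - 2L
  }
  t <- diff / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  # zero pooled variance with unequal means: the t statistic diverges
  inf <- !skip & se2 == 0 & diff != 0
  t[inf] <- sign(diff[inf]) * Inf
  p[inf] <- 0
  t[skip] <- NA_real_
  p[skip] <- NA_real_
  data.frame(
    target_gene = rownames(values),
    t_stat = t,
    p_value = p,
    direction = ifelse(diff < 0, "sensitive",
                       ifelse(diff > 0, "resistant", NA_character_)),
    n_case = a$n, n_control = b$n,
    skip = skip,
    stringsAsFactors = FALSE
  )
}

#' Test a single (mutated gene, target gene) pair
#'
#' Compares the depletion scores of the target gene between case cells
#' (carrying a functional mutation in the query gene) and control cells by a
#' two-sided Welch or Student t-test. The direction is `"sensitive"` when the
#' case mean is lower (knockout kills mutants preferentially) and
#' `"resistant"` when higher.
#'
#' @param depletion_row named numeric vector of the target gene's depletion
#'   scores (may contain `NA` for missing or masked entries).
#' @param mutation_row 0/1 (or logical) vector over the same cells marking
#'   case membership.
#' @param config a [gi_test_config()].
#' @return a list `(t_stat, p_value, direction, n_case, n_control)`, or
#'   `NULL` when the pair is skipped (a group smaller than
#'   `min_group_size`, or both groups constant with equal means).
#' @export
test_pair <- function(depletion_row, mutation_row, config = gi_test_config()) {
  stopifnot(length(depletion_row) == length(mutation_row))
  res <- row_t_test(matrix(depletion_row, nrow = 1L,
                           dimnames = list("K", names(depletion_row))),
                    as.logical(mutation_row),
                    t_variant = config$t_variant,
                    min_group_size = config$min_group_size)
  if (res$skip[1L]) return(NULL)
  list(t_stat = res$t_stat[1L], p_value = res$p_value[1L],
       direction = res$direction[1L],
       n_case = res$n_case[1L], n_control = res$n_control[1L])
}

#' Benjamini-Hochberg adjusted FDR values
#'
#' Step-up BH adjustment with an explicit family size `M`, which may exceed
#' the number of p-values supplied (pairs skipped for degenerate groups are
#' not part of the family and must not inflate it, but the family covers all
#' tests actually performed in one screening, jointly across both
#' directions).
#'
#' @param p_values numeric vector of two-sided p-values in `[0, 1]`.
#' @param M family size (default: `length(p_values)`).
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values, M = length(p_values)) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (M < length(p_values)) stop("family size M below number of p-values",
                                 call. = FALSE)
  stats::p.adjust(p_values, method = "BH", n = M)
}

#' Characterize genetic interactions by differential essentiality
#'
#' Iterates every pair of a recurrently mutated gene Q and a screened gene K,
#' tests K's depletion scores between Q-mutant and Q-wild-type cell lines
#' ([test_pair()] semantics, vectorized), adjusts all obtained p-values in
#' one BH family, and returns the pairs with FDR below the threshold.
#'
#' @param depletion genes x cells depletion [score_matrix()].
#' @param mutation_matrix binary genes x cells matrix from
#'   [call_functional_mutations()].
#' @param recurrent_genes mutated genes Q to screen (e.g. from
#'   [select_recurrent_genes()]); genes without a row in `mutation_matrix`
#'   are dropped with a message.
#' @param expression optional expression [score_matrix()] for the exclusion
#'   procedure; ignored when `config$exclusion` is `FALSE`.
#' @param config a [gi_test_config()].
#' @param keep_all return all tested pairs instead of only those below the
#'   FDR threshold (used for diagnostics).
#' @return a GI table (`data.frame` subclass) ordered by mutated then target
#'   gene, with attributes `n_tests` (BH family size M) and `n_skipped`.
#' @export
characterize_gis <- function(depletion, mutation_matrix, recurrent_genes,
                             expression = NULL, config = gi_test_config(),
                             keep_all = FALSE) {
  recurrent_genes <- as.character(recurrent_genes)
  missing_q <- setdiff(recurrent_genes, rownames(mutation_matrix))
  if (length(missing_q)) {
    message("dropping ", length(missing_q),
            " recurrent gene(s) absent from the mutation matrix")
    recurrent_genes <- setdiff(recurrent_genes, missing_q)
  }
  if (length(recurrent_genes) == 0L) {
    stop("no recurrently mutated genes to screen", call. = FALSE)
  }
  if (nrow(depletion) == 0L) stop("no screened genes", call. = FALSE)

  cells <- align_cells(depletion, mutation_matrix)
  dep_raw <- depletion[, cells, drop = FALSE]
  dep <- dep_raw
  if (config$exclusion && !is.null(expression)) {
    dep <- mask_nonexpressed(dep, expression, config$expression_zero_epsilon)
  }

  per_q <- lapply(sort(recurrent_genes), function(q) {
    case <- mutation_matrix[q, cells] == 1L
    res <- row_t_test(dep, case, t_variant = config$t_variant,
                      min_group_size = config$min_group_size)
    # group sizes before masking, to report how many scores were excluded
    raw_case <- rowSums(!is.na(dep_raw[, case, drop = FALSE]))
    raw_ctrl <- rowSums(!is.na(dep_raw[, !case, drop = FALSE]))
    res$n_masked_case <- raw_case - res$n_case
    res$n_masked_control <- raw_ctrl - res$n_control
    res$mutated_gene <- q
    res
  })
  all_res <- do.call(rbind, per_q)
  tested <- all_res[!all_res$skip, , drop = FALSE]
  n_skipped <- sum(all_res$skip)
  M <- nrow(tested)
  if (M > 0L) {
    tested$fdr <- bh_fdr(tested$p_value, M)
  } else {
    tested$fdr <- numeric(0)
  }
  out <- if (keep_all) tested else
    tested[tested$fdr < config$fdr_threshold, , drop = FALSE]
  out <- out[order(out$mutated_gene, out$target_gene), , drop = FALSE]
  new_gi_table(out, n_tests = M, n_skipped = n_skipped, config = config)
}
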