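#' @keywords internal
"_PACKAGE"

#' Strip a trailing parenthetical identifier from gene labels
#'
#' DepMap-style matrices label genes as `"BRAF (673)"` (HUGO symbol plus an
#' Entrez ID). Matching across mutation, screen, expression and network gene
#' spaces is by bare symbol, so trailing parenthetical tokens are removed
#' (repeatedly, so the operation is idempotent; real labels carry at most
#' one).
#'
#' @param x character vector of gene labels.
#' @return character vector of bare gene symbols.
#' @examples
#' strip_gene_suffix(c("BRAF (673)", "TP53", "NKX2-1 (7080)"))
#' @export
strip_gene_suffix <- function(x) {
  x <- trimws(x)
  repeat {
    stripped <- sub("\\s*\\([^()]*\\)\\s*$", "", x)
    if (identical(stripped, x)) return(stripped)
    x <- stripped
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Guess the field separator of a delimited text file from its first line.
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("file is empty: ", path, call. = FALSE)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

# shared number formatter: round-trips doubles through text at full precision
format_num <- function(x) {
  ifelse(is.na(x), "NA", format(x, digits = 15L, scientific = TRUE, trim = TRUE))
}
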