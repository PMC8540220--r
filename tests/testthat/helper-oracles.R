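# Independent oracles used across the suite. Each is a direct transcription
# of the textbook definition, deliberately scalar/naive, so it shares no code
# path with the package implementation it checks.

# Welch two-sample t-test: Welch-Satterthwaite statistic, two-sided p.
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1); v2 <- sum((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Student two-sample t-test with pooled variance.
oracle_student <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1); v2 <- sum((y - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Benjamini-Hochberg adjusted values by the direct min-over-tail formula:
# adj_i = min_{j : p_(j) >= p_(i)} p_(j) * M / rank(j), capped at 1.
oracle_bh <- function(p, M = length(p)) {
  o <- order(p)
  ranked <- p[o]
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ranked[i:m] * M / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Reachability within k steps by boolean adjacency-matrix powers.
# Returns the boolean matrix R with R[i, j] TRUE iff a path of length in
# 1..k runs from node i to node j under the direction mode.
oracle_reach <- function(edges, nodes, k, directed, mode = "either") {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    A[cbind(match(edges[[1]], nodes), match(edges[[2]], nodes))] <- TRUE
    if (!directed) A[cbind(match(edges[[2]], nodes),
                           match(edges[[1]], nodes))] <- TRUE
  }
  diag(A) <- FALSE
  base <- if (directed && mode == "ignore") A | t(A) else A
  R <- base
  P <- base
  if (k >= 2) {
    for (i in 2:k) {
      P <- (P %*% base) > 0
      R <- R | P
    }
  }
  diag(R) <- FALSE
  if (directed && mode == "either") R <- R | t(R)
  R
}

# Random edge list on `n` named nodes with edge probability `p`.
random_edges <- function(n, p, node_prefix = "G") {
  nodes <- paste0(node_prefix, seq_len(n))
  cmb <- t(combn(nodes, 2))
  # both orientations possible for directed graphs
  cand <- rbind(cmb, cmb[, 2:1])
  pick <- runif(nrow(cand)) < p
  list(nodes = nodes,
       edges = data.frame(from = cand[pick, 1], to = cand[pick, 2],
                          stringsAsFactors = FALSE))
}

igraph_from_edges <- function(edges, nodes, directed) {
  igraph::graph_from_data_frame(edges, directed = directed,
                                vertices = data.frame(name = nodes))
}

# Small screening fixture: planted shift delta for the (Q, K) pairs listed
# in `planted` (data.frame mutated_gene, target_gene, direction).
tiny_screen <- function(n_cells = 60, genes = paste0("K", 1:8),
                        q_genes = "Q1", pi = 0.25, sigma = 0.2, delta = 1,
                        planted = NULL, seed = 1) {
  set.seed(seed)
  cells <- sprintf("C%03d", seq_len(n_cells))
  dep <- matrix(rnorm(length(genes) * n_cells, 0, sigma),
                nrow = length(genes), dimnames = list(genes, cells))
  mut <- matrix(0L, nrow = length(q_genes), ncol = n_cells,
                dimnames = list(q_genes, cells))
  for (q in q_genes) {
    idx <- which(runif(n_cells) < pi)
    if (length(idx) < 3) idx <- 1:5
    mut[q, idx] <- 1L
  }
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      sgn <- if (planted$direction[i] == "sensitive") -1 else 1
      cc <- mut[planted$mutated_gene[i], ] == 1
      dep[planted$target_gene[i], cc] <- dep[planted$target_gene[i], cc] +
        sgn * delta
    }
  }
  list(depletion = score_matrix(dep, "depletion"), mutation = mut,
       cells = cells)
}
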