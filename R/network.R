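# Gene networks (KEGG-style directed, PPI-style undirected) as igraph
# objects: loading from edge lists, bounded-distance queries, and the
# refining process (RP) over synthetic-partner sets.

#' Load a gene network from a two-column edge list
#'
#' Accepts TSV with `source<TAB>target` (optional extra attribute columns and
#' an optional header line are tolerated). Duplicate edges under the
#' network's directedness convention and self-loops are dropped, with counts
#' reported via `message()`.
#'
#' @param path edge-list TSV.
#' @param directed `TRUE` for KEGG-style directed edges, `FALSE` for
#'   PPI-style undirected ones.
#' @return an `igraph` graph.
#' @export
load_network <- function(path, directed) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty network file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed edge at line ", bad[1L], " of ", path,
         " (need at least two tab-separated fields)", call. = FALSE)
  }
  u <- vapply(parts, `[[`, "", 1L)
  v <- vapply(parts, `[[`, "", 2L)
  header_names <- list(c("source", "target"), c("from", "to"),
                       c("gene1", "gene2"))
  if (any(vapply(header_names, function(h)
    identical(tolower(c(u[1L], v[1L])), h), TRUE))) {
    u <- u[-1L]
    v <- v[-1L]
  }
  if (length(u) == 0L) stop("network file has no edges: ", path, call. = FALSE)
  loops <- u == v
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    u <- u[!loops]
    v <- v[!loops]
  }
  g <- igraph::graph_from_data_frame(data.frame(from = u, to = v,
                                                stringsAsFactors = FALSE),
                                     directed = directed)
  before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(g) < before) {
    message("dropped ", before - igraph::ecount(g), " duplicate edge(s)")
  }
  g
}

# Pairwise shortest-path distances among `from` and `to` node-name vectors
# under a direction mode; names absent from the graph yield Inf.
#   ignore  — treat every edge as undirected
#   either  — a directed path in either orientation counts (min of the two)
#   forward — directed paths from the row node to the column node only
network_distances <- function(network, from, to, direction_mode = "either") {
  direction_mode <- match.arg(direction_mode, c("either", "ignore", "forward"))
  nodes <- igraph::V(network)$name
  D <- matrix(Inf, nrow = length(from), ncol = length(to),
              dimnames = list(from, to))
  fi <- from[from %in% nodes]
  ti <- to[to %in% nodes]
  if (length(fi) == 0L || length(ti) == 0L) return(D)
  if (direction_mode == "ignore" && igraph::is_directed(network)) {
    g <- igraph::as_undirected(network, mode = "collapse")
    D[fi, ti] <- igraph::distances(g, v = fi, to = ti,
                                   algorithm = "unweighted")
  } else if (direction_mode == "either" && igraph::is_directed(network)) {
    out <- igraph::distances(network, v = fi, to = ti, mode = "out",
                             algorithm = "unweighted")
    inn <- igraph::distances(network, v = fi, to = ti, mode = "in",
                             algorithm = "unweighted")
    D[fi, ti] <- pmin(out, inn)
  } else {
    D[fi, ti] <- igraph::distances(network, v = fi, to = ti, mode = "out",
                                   algorithm = "unweighted")
  }
  D
}

#' Is any target within network distance k of a source gene?
#'
#' Breadth-first shortest-path distances, bounded at `k`. The source itself is
#' never its own target. A source absent from the network yields `FALSE`.
#'
#' @param network an `igraph` graph from [load_network()].
#' @param source gene symbol.
#' @param targets character vector of candidate genes.
#' @param k maximum path length (1 or 2 in the refining process).
#' @param direction_mode `"either"` (a directed path in either orientation
#'   confers proximity; the default, since adjacency of synthetic partners is
#'   a symmetric notion), `"ignore"` (treat edges as undirected) or
#'   `"forward"` (source-to-target paths only). Immaterial on undirected
#'   networks.
#' @return single logical.
#' @export
within_distance <- function(network, source, targets, k,
                            direction_mode = "either") {
  stopifnot(k >= 1)
  targets <- setdiff(targets, source)
  if (length(targets) == 0L) return(FALSE)
  if (!source %in% igraph::V(network)$name) {
    message("source gene '", source, "' not in network")
    return(FALSE)
  }
  D <- network_distances(network, source, targets, direction_mode)
  any(D <= k)
}

#' Map the synthetic partners of each mutated gene onto a network
#'
#' For each mutated gene Q in the GI table, the initial SP set is its target
#' genes that are network nodes. Mutated genes with fewer than `min_sps`
#' mapped SPs are flagged skipped: the refining process needs at least two
#' SPs to ask whether they are mutually close.
#'
#' @param gi_table GI table from [characterize_gis()].
#' @param network an `igraph` graph.
#' @param min_sps minimum mapped SPs (default 2).
#' @return named list per mutated gene: `mutated_gene`, `initial` (mapped SP
#'   symbols), `n_unmapped`, `skipped`.
#' @export
map_sps <- function(gi_table, network, min_sps = 2L) {
  nodes <- igraph::V(network)$name
  qs <- unique(gi_table$mutated_gene)
  res <- lapply(qs, function(q) {
    ks <- unique(gi_table$target_gene[gi_table$mutated_gene == q])
    mapped <- sort(intersect(ks, nodes))
    list(mutated_gene = q,
         initial = mapped,
         n_unmapped = length(ks) - length(mapped),
         skipped = length(mapped) < min_sps)
  })
  names(res) <- qs
  total_unmapped <- sum(vapply(res, `[[`, 0L, "n_unmapped"))
  if (total_unmapped > 0L) {
    message(total_unmapped, " SP(s) not present in the network across ",
            length(qs), " mutated gene(s)")
  }
  res[order(names(res))]
}

#' Refine a synthetic-partner set by network proximity (RP)
#'
#' An SP is retained iff some *other* member of the initial SP set lies
#' within network distance `k`. The pass is evaluated against the original
#' initial set, not iterated: an SP whose only near neighbor is itself
#' removed still survives. `fixed_point = TRUE` selects the iterative
#' variant, re-applying the rule to the retained set until stable.
#'
#' @param initial_sps character vector of mapped SP symbols (length >= 2).
#' @param network an `igraph` graph.
#' @param k distance cutoff: 1 (RP1) or 2 (RP2).
#' @param direction_mode see [within_distance()].
#' @param fixed_point iterate the filter to a fixed point.
#' @return list with `mutated_gene` (filled by callers), `initial`,
#'   `retained`, `removed`, `k`, `skipped`.
#' @export
refine_sps <- function(initial_sps, network, k, direction_mode = "either",
                       fixed_point = FALSE) {
  initial_sps <- sort(unique(initial_sps))
  if (length(initial_sps) < 2L) {
    return(list(initial = initial_sps, retained = character(0),
                removed = initial_sps, k = k, skipped = TRUE))
  }
  keep_pass <- function(sps) {
    D <- network_distances(network, sps, sps, direction_mode)
    diag(D) <- Inf
    sps[apply(D, 1L, min) <= k]
  }
  retained <- keep_pass(initial_sps)
  if (fixed_point) {
    repeat {
      nxt <- if (length(retained) >= 2L) keep_pass(retained) else character(0)
      if (identical(nxt, retained)) break
      retained <- nxt
    }
  }
  list(initial = initial_sps, retained = retained,
       removed = setdiff(initial_sps, retained), k = k, skipped = FALSE)
}

#' Apply the refining process to a whole GI table
#'
#' Maps every mutated gene's SPs onto the network, builds the initial-stage
#' table (mutated genes with at least `min_sps` mapped SPs), and filters it
#' at each requested distance. Stage tables are nested:
#' `RP1 ` \eqn{\subseteq} ` RP2 ` \eqn{\subseteq} ` INIT`.
#'
#' @param gi_table GI table from [characterize_gis()].
#' @param network an `igraph` graph.
#' @param distances distance cutoffs to apply (default `c(2, 1)`).
#' @param direction_mode see [within_distance()].
#' @param min_sps minimum mapped SPs per mutated gene (default 2).
#' @param fixed_point see [refine_sps()].
#' @return list with `tables` (named `INIT`, and `RP<k>` per distance) and
#'   `refinements` (per mutated gene, per distance [refine_sps()] results).
#' @export
refine_gis <- function(gi_table, network, distances = c(2L, 1L),
                       direction_mode = "either", min_sps = 2L,
                       fixed_point = FALSE) {
  sps <- map_sps(gi_table, network, min_sps = min_sps)
  active <- sps[!vapply(sps, `[[`, TRUE, "skipped")]

  subset_table <- function(keep_map) {
    keep <- if (nrow(gi_table) == 0L) logical(0) else
      mapply(function(q, k) {
        q %in% names(keep_map) && k %in% keep_map[[q]]
      }, gi_table$mutated_gene, gi_table$target_gene)
    new_gi_table(as.data.frame(gi_table)[keep, , drop = FALSE],
                 n_tests = attr(gi_table, "n_tests") %||% nrow(gi_table),
                 n_skipped = attr(gi_table, "n_skipped") %||% 0L,
                 config = attr(gi_table, "config"))
  }

  init_map <- lapply(active, `[[`, "initial")
  tables <- list(INIT = subset_table(init_map))
  refinements <- list()
  for (k in distances) {
    refs <- lapply(active, function(s) {
      r <- refine_sps(s$initial, network, k, direction_mode = direction_mode,
                      fixed_point = fixed_point)
      r$mutated_gene <- s$mutated_gene
      r
    })
    refinements[[paste0("RP", k)]] <- refs
    tables[[paste0("RP", k)]] <- subset_table(lapply(refs, `[[`, "retained"))
  }
  list(tables = tables, refinements = refinements, sps = sps)
}
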