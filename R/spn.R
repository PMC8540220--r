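# Synthetic partner networks: the subnetwork over a mutated gene's retained
# SPs, plus (at distance 2) the non-SP connector genes linking them.

#' Build the synthetic partner network (SPN) of one mutated gene
#'
#' SP nodes are the SPs retained by the refining process at distance `k`,
#' labeled with their GI direction (sensitive/resistant) and FDR. Edges
#' between two SP nodes are included directly. At `k = 2`, a non-SP node `w`
#' joins as a connector when its edges realize a length-2 path between two
#' distinct retained SPs consistent with the direction mode, and the two
#' realizing edges are included; at `k = 1` the connector set is empty by
#' construction.
#'
#' @param refinement a [refine_sps()] result carrying `mutated_gene` and
#'   `retained` (as produced inside [refine_gis()]), or a character vector of
#'   retained SPs together with `mutated_gene`.
#' @param network an `igraph` graph.
#' @param gi_table GI table supplying direction and FDR annotations.
#' @param k the refinement distance the SPN corresponds to (1 or 2).
#' @param direction_mode see [within_distance()].
#' @param mutated_gene required when `refinement` is a plain character
#'   vector.
#' @return an `spn` object: list with `mutated_gene`, `k`, `nodes`
#'   (data.frame `gene`, `role` in sensitive/resistant/connector, `fdr`),
#'   `edges` (data.frame `from`, `to`), `directed`.
#' @export
build_spn <- function(refinement, network, gi_table, k,
                      direction_mode = "either", mutated_gene = NULL) {
  if (is.character(refinement)) {
    retained <- refinement
    q <- mutated_gene
    if (is.null(q)) stop("mutated_gene required", call. = FALSE)
  } else {
    retained <- refinement$retained
    q <- refinement$mutated_gene %||% mutated_gene
    if (is.null(q)) stop("mutated_gene required", call. = FALSE)
  }
  directed <- igraph::is_directed(network)
  nodes <- igraph::V(network)$name
  retained <- sort(intersect(retained, nodes))

  ann <- gi_table[gi_table$mutated_gene == q, c("target_gene", "direction",
                                                "fdr"), drop = FALSE]
  ann <- ann[!duplicated(ann$target_gene), , drop = FALSE]

  empty_edges <- data.frame(from = character(0), to = character(0),
                            stringsAsFactors = FALSE)
  sp_edges <- empty_edges
  conn_edges <- empty_edges
  connectors <- character(0)

  if (length(retained) >= 1L) {
    sub <- igraph::induced_subgraph(network, retained)
    sp_edges <- igraph::as_data_frame(sub, what = "edges")[, c("from", "to")]
    if (k >= 2L && length(retained) >= 2L) {
      ce <- connector_edges(network, retained, direction_mode)
      connectors <- ce$connectors
      conn_edges <- ce$edges
    }
  }

  edges <- unique(rbind(sp_edges, conn_edges))
  if (!directed && nrow(edges)) {
    # canonical endpoint order for undirected edges
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- unique(edges)
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  node_df <- data.frame(
    gene = c(retained, connectors),
    role = c(ann$direction[match(retained, ann$target_gene)],
             rep("connector", length(connectors))),
    fdr = c(ann$fdr[match(retained, ann$target_gene)],
            rep(NA_real_, length(connectors))),
    stringsAsFactors = FALSE
  )
  node_df <- node_df[order(node_df$role == "connector", node_df$gene), ,
                     drop = FALSE]
  rownames(node_df) <- NULL

  structure(list(mutated_gene = q, k = as.integer(k), nodes = node_df,
                 edges = edges, directed = directed),
            class = "spn")
}

# Non-SP nodes whose edges realize a length-2 path between two distinct SPs
# under the direction mode, with the realizing edges. On undirected graphs
# (or mode "ignore") w qualifies iff adjacent to >= 2 SPs. On directed
# graphs, modes "either" and "forward" both require SP -> w -> SP' (a
# reversed 2-path under "either" is the forward 2-path of the swapped pair,
# so the qualifying w and edge sets coincide).
connector_edges <- function(network, retained, direction_mode) {
  directed <- igraph::is_directed(network)
  empty <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  if (!directed || direction_mode == "ignore") {
    g <- if (directed) igraph::as_undirected(network, mode = "collapse")
         else network
    nb <- igraph::adjacent_vertices(g, retained, mode = "all")
    cand <- setdiff(unique(unlist(lapply(nb, function(v) v$name))), retained)
    edges <- empty
    connectors <- character(0)
    for (w in cand) {
      adj <- igraph::neighbors(g, w, mode = "all")$name
      sps <- sort(intersect(adj, retained))
      if (length(sps) >= 2L) {
        connectors <- c(connectors, w)
        edges <- rbind(edges, data.frame(from = sps, to = w,
                                         stringsAsFactors = FALSE))
      }
    }
    return(list(connectors = sort(connectors), edges = edges))
  }
  nb_out <- igraph::adjacent_vertices(network, retained, mode = "out")
  nb_in <- igraph::adjacent_vertices(network, retained, mode = "in")
  cand <- setdiff(unique(c(unlist(lapply(nb_out, function(v) v$name)),
                           unlist(lapply(nb_in, function(v) v$name)))),
                  retained)
  edges <- empty
  connectors <- character(0)
  for (w in cand) {
    into_w <- intersect(igraph::neighbors(network, w, mode = "in")$name,
                        retained)   # SPs s with s -> w
    from_w <- intersect(igraph::neighbors(network, w, mode = "out")$name,
                        retained)   # SPs t with w -> t
    # pairs (s, t), s != t, realizing s -> w -> t
    ok_in <- into_w[vapply(into_w, function(s)
      length(setdiff(from_w, s)) > 0L, TRUE)]
    ok_out <- from_w[vapply(from_w, function(t)
      length(setdiff(into_w, t)) > 0L, TRUE)]
    if (length(ok_in) && length(ok_out)) {
      connectors <- c(connectors, w)
      edges <- rbind(edges,
                     data.frame(from = ok_in, to = w,
                                stringsAsFactors = FALSE),
                     data.frame(from = w, to = ok_out,
                                stringsAsFactors = FALSE))
    }
  }
  list(connectors = sort(connectors), edges = unique(edges))
}

#' @export
print.spn <- function(x, ...) {
  n_conn <- sum(x$nodes$role == "connector")
  cat("SPN", x$k, " for mutated ", x$mutated_gene, ": ",
      nrow(x$nodes) - n_conn, " SPs (",
      sum(x$nodes$role == "sensitive"), " sensitive, ",
      sum(x$nodes$role == "resistant"), " resistant), ",
      n_conn, " connectors, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Export / import an SPN
#'
#' Formats: `"tsv"` (node and edge records in one file; re-importable via
#' [import_spn()]), `"sif"` (Cytoscape simple interaction format), and
#' `"graphml"` (node attributes `role` and `fdr`).
#'
#' @param spn an [build_spn()] result.
#' @param path output file.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_spn <- function(spn, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\tinteracts\t%s", spn$edges$from, spn$edges$to)
    writeLines(lines, path)
  } else if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# spn mutated_gene=%s k=%d directed=%s",
                       spn$mutated_gene, spn$k, spn$directed), con)
    writeLines("record\tfrom\tto\trole\tfdr", con)
    if (nrow(spn$nodes)) {
      writeLines(sprintf("node\t%s\t\t%s\t%s", spn$nodes$gene, spn$nodes$role,
                         format_num(spn$nodes$fdr)), con)
    }
    if (nrow(spn$edges)) {
      writeLines(sprintf("edge\t%s\t%s\t\t", spn$edges$from, spn$edges$to),
                 con)
    }
  } else {
    g <- igraph::graph_from_data_frame(
      spn$edges, directed = spn$directed,
      vertices = data.frame(name = spn$nodes$gene, role = spn$nodes$role,
                            fdr = ifelse(is.na(spn$nodes$fdr), -1,
                                         spn$nodes$fdr),
                            stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_spn
#' @export
import_spn <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1L], "# spn")) {
    stop("not an SPN tsv export: ", path, call. = FALSE)
  }
  hdr <- lines[1L]
  get <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1L]]
    m[2L]
  }
  body <- lines[-(1:2)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  pad <- function(p) c(p, rep("", 5L - length(p)))[1:5]
  parts <- lapply(parts, pad)
  rec <- vapply(parts, `[[`, "", 1L)
  nodes <- parts[rec == "node"]
  edges <- parts[rec == "edge"]
  node_df <- data.frame(
    gene = vapply(nodes, `[[`, "", 2L),
    role = vapply(nodes, `[[`, "", 4L),
    fdr = suppressWarnings(as.numeric(vapply(nodes, `[[`, "", 5L))),
    stringsAsFactors = FALSE
  )
  edge_df <- data.frame(
    from = vapply(edges, `[[`, "", 2L),
    to = vapply(edges, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  structure(list(mutated_gene = get("mutated_gene"),
                 k = as.integer(get("k")),
                 nodes = node_df, edges = edge_df,
                 directed = identical(get("directed"), "TRUE")),
            class = "spn")
}
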