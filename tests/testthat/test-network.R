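write_edges <- function(edges, header = TRUE) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  lines <- sprintf("%s\t%s", edges[[1]], edges[[2]])
  if (header) lines <- c("source\ttarget", lines)
  writeLines(lines, f)
  f
}

test_that("edge lists load with deduplication, directedness and self-loop removal", {
  f <- write_edges(data.frame(a = c("A", "B", "A"), b = c("B", "A", "A")))
  suppressMessages(g_un <- load_network(f, directed = FALSE))
  expect_equal(igraph::ecount(g_un), 1)
  suppressMessages(g_di <- load_network(f, directed = TRUE))
  expect_equal(igraph::ecount(g_di), 2)
  expect_true(igraph::is_directed(g_di))
  expect_message(load_network(f, directed = FALSE), "self-loop")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "oops"), bad)
  expect_error(load_network(bad, directed = FALSE), "line 2")
})

test_that("within_distance obeys the distance bound and direction modes", {
  g <- igraph_from_edges(data.frame(from = c("A", "x"), to = c("x", "C")),
                         c("A", "x", "C", "Z"), directed = FALSE)
  expect_true(within_distance(g, "A", "C", k = 2))
  expect_false(within_distance(g, "A", "C", k = 1))
  # matches boolean adjacency powers on the same toy graph
  R2 <- oracle_reach(data.frame(from = c("A", "x"), to = c("x", "C")),
                     c("A", "x", "C", "Z"), k = 2, directed = FALSE)
  expect_true(R2["A", "C"])

  gd <- igraph_from_edges(data.frame(from = "A", to = "B"),
                          c("A", "B"), directed = TRUE)
  expect_true(within_distance(gd, "B", "A", k = 1, direction_mode = "either"))
  expect_false(within_distance(gd, "B", "A", k = 1,
                               direction_mode = "forward"))
  expect_true(within_distance(gd, "B", "A", k = 1, direction_mode = "ignore"))

  # the source is never its own target; absent sources are FALSE
  expect_false(within_distance(g, "A", "A", k = 2))
  expect_false(suppressMessages(within_distance(g, "Q", "A", k = 2)))
})

test_that("refine keeps exactly the SPs with another SP within distance k", {
  g <- igraph_from_edges(data.frame(from = "A", to = "B"),
                         c("A", "B", "C"), directed = FALSE)
  r <- refine_sps(c("A", "B", "C"), g, k = 1)
  expect_equal(r$retained, c("A", "B"))
  expect_equal(r$removed, "C")
  expect_false(r$skipped)

  # mutually distant SPs: nothing survives even at distance 2
  g2 <- igraph_from_edges(
    data.frame(from = c("A", "x", "y"), to = c("x", "y", "B")),
    c("A", "x", "y", "B"), directed = FALSE)
  r2 <- refine_sps(c("A", "B"), g2, k = 2)
  expect_equal(r2$retained, character(0))

  # a connected clique is fully retained at both distances
  cl <- t(combn(c("A", "B", "C", "D"), 2))
  g3 <- igraph_from_edges(data.frame(from = cl[, 1], to = cl[, 2]),
                          c("A", "B", "C", "D"), directed = FALSE)
  for (k in 1:2) {
    expect_equal(refine_sps(c("A", "B", "C", "D"), g3, k = k)$retained,
                 c("A", "B", "C", "D"))
  }

  # fewer than two SPs: flagged skipped
  expect_true(refine_sps("A", g, k = 1)$skipped)
  # input order does not matter
  expect_equal(refine_sps(c("C", "B", "A"), g, k = 1)$retained,
               r$retained)
})

test_that("single-pass refinement differs from the fixed-point variant only through asymmetry", {
  # forward mode on A -> B: A sees B, B sees nothing
  gd <- igraph_from_edges(data.frame(from = "A", to = "B"),
                          c("A", "B"), directed = TRUE)
  single <- refine_sps(c("A", "B"), gd, k = 1, direction_mode = "forward")
  expect_equal(single$retained, "A")
  fp <- refine_sps(c("A", "B"), gd, k = 1, direction_mode = "forward",
                   fixed_point = TRUE)
  expect_equal(fp$retained, character(0))
  # under the symmetric default the two variants agree
  gu <- igraph_from_edges(data.frame(from = c("A", "B"), to = c("B", "C")),
                          c("A", "B", "C", "D"), directed = FALSE)
  expect_equal(refine_sps(c("A", "B", "C", "D"), gu, k = 1)$retained,
               refine_sps(c("A", "B", "C", "D"), gu, k = 1,
                          fixed_point = TRUE)$retained)
})

test_that("SP mapping restricts to network nodes and flags undersized sets", {
  gi <- girefine:::new_gi_table(data.frame(
    mutated_gene = c("Q1", "Q1", "Q1", "Q2"),
    target_gene = c("K1", "K2", "K3", "K9"),
    direction = "sensitive", t_stat = -3, p_value = 0.001, fdr = 0.01,
    n_case = 5, n_control = 20, n_masked_case = 0, n_masked_control = 0),
    n_tests = 4)
  g <- igraph_from_edges(data.frame(from = "K1", to = "K3"),
                         c("K1", "K3", "K9"), directed = FALSE)
  suppressMessages(m <- map_sps(gi, g))
  expect_equal(m$Q1$initial, c("K1", "K3"))
  expect_equal(m$Q1$n_unmapped, 1L)
  expect_false(m$Q1$skipped)
  expect_true(m$Q2$skipped)
})

test_that("SPNs contain retained SPs, annotated roles, and distance-2 connectors", {
  gi <- girefine:::new_gi_table(data.frame(
    mutated_gene = "Q1", target_gene = c("A", "C"),
    direction = c("sensitive", "resistant"),
    t_stat = c(-4, 4), p_value = 0.001, fdr = c(0.01, 0.05),
    n_case = 5, n_control = 20, n_masked_case = 0, n_masked_control = 0),
    n_tests = 2)
  g <- igraph_from_edges(data.frame(from = c("A", "x"), to = c("x", "C")),
                         c("A", "x", "C"), directed = FALSE)
  spn2 <- build_spn(c("A", "C"), g, gi, k = 2, mutated_gene = "Q1")
  expect_setequal(spn2$nodes$gene, c("A", "C", "x"))
  expect_equal(spn2$nodes$role[spn2$nodes$gene == "A"], "sensitive")
  expect_equal(spn2$nodes$role[spn2$nodes$gene == "C"], "resistant")
  expect_equal(spn2$nodes$role[spn2$nodes$gene == "x"], "connector")
  expect_equal(spn2$nodes$fdr[spn2$nodes$gene == "A"], 0.01)
  expect_equal(nrow(spn2$edges), 2L)

  # k = 1: no connectors by construction
  spn1 <- build_spn(c("A", "C"), g, gi, k = 1, mutated_gene = "Q1")
  expect_false("connector" %in% spn1$nodes$role)
  # empty retained set: valid empty SPN
  spn0 <- build_spn(character(0), g, gi, k = 2, mutated_gene = "Q1")
  expect_equal(nrow(spn0$nodes), 0L)
  expect_equal(nrow(spn0$edges), 0L)
})

test_that("directed connectors require a two-path in a mode-consistent orientation", {
  gi <- girefine:::new_gi_table(data.frame(
    mutated_gene = "Q1", target_gene = c("A", "C"),
    direction = "sensitive", t_stat = -4, p_value = 0.001, fdr = 0.01,
    n_case = 5, n_control = 20, n_masked_case = 0, n_masked_control = 0),
    n_tests = 2)
  # A -> w -> C: a directed 2-path, qualifies under "either"
  g1 <- igraph_from_edges(data.frame(from = c("A", "w"), to = c("w", "C")),
                          c("A", "w", "C"), directed = TRUE)
  s1 <- build_spn(c("A", "C"), g1, gi, k = 2, mutated_gene = "Q1")
  expect_true("w" %in% s1$nodes$gene)
  # A -> w <- C: no directed 2-path between A and C in either orientation
  g2 <- igraph_from_edges(data.frame(from = c("A", "C"), to = c("w", "w")),
                          c("A", "w", "C"), directed = TRUE)
  s2 <- build_spn(c("A", "C"), g2, gi, k = 2, mutated_gene = "Q1")
  expect_false("w" %in% s2$nodes$gene)
  # but it does qualify when edge direction is ignored
  s3 <- build_spn(c("A", "C"), g2, gi, k = 2, mutated_gene = "Q1",
                  direction_mode = "ignore")
  expect_true("w" %in% s3$nodes$gene)
})

test_that("SPN exports round-trip (tsv) and render SIF/GraphML", {
  gi <- girefine:::new_gi_table(data.frame(
    mutated_gene = "Q1", target_gene = c("A", "C"),
    direction = c("sensitive", "resistant"),
    t_stat = c(-4, 4), p_value = 0.001, fdr = c(0.012345678901, 0.05),
    n_case = 5, n_control = 20, n_masked_case = 0, n_masked_control = 0),
    n_tests = 2)
  g <- igraph_from_edges(data.frame(from = c("A", "x"), to = c("x", "C")),
                         c("A", "x", "C"), directed = FALSE)
  spn <- build_spn(c("A", "C"), g, gi, k = 2, mutated_gene = "Q1")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_spn(spn, tsv, "tsv")
  back <- import_spn(tsv)
  expect_equal(back$nodes$gene, spn$nodes$gene)
  expect_equal(back$nodes$role, spn$nodes$role)
  expect_equal(back$edges, spn$edges)
  expect_equal(back$k, 2L)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_spn(spn, sif, "sif")
  expect_equal(length(readLines(sif)), nrow(spn$edges))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_spn(spn, gml, "graphml")
  gback <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(gback)$name, spn$nodes$gene)
  expect_setequal(igraph::V(gback)$role,
                  unique(spn$nodes$role))

  # empty SPN: valid file with header
  spn0 <- build_spn(character(0), g, gi, k = 1, mutated_gene = "Q1")
  export_spn(spn0, tsv, "tsv")
  expect_equal(nrow(import_spn(tsv)$nodes), 0L)
})

test_that("every SPN node satisfies its defining property on random graphs", {
  set.seed(19)
  for (rep in 1:10) {
    re <- random_edges(25, 0.08)
    directed <- rep %% 2 == 0
    g <- igraph_from_edges(re$edges, re$nodes, directed = directed)
    sps <- sample(re$nodes, 8)
    gi <- girefine:::new_gi_table(data.frame(
      mutated_gene = "Q", target_gene = sps, direction = "sensitive",
      t_stat = -3, p_value = 0.001, fdr = 0.01, n_case = 5, n_control = 10,
      n_masked_case = 0, n_masked_control = 0), n_tests = 8)
    for (k in 1:2) {
      r <- refine_sps(sps, g, k = k)
      spn <- build_spn(r, g, gi, k = k, mutated_gene = "Q")
      sp_nodes <- spn$nodes$gene[spn$nodes$role != "connector"]
      for (s in sp_nodes) {
        expect_true(within_distance(g, s, setdiff(sp_nodes, s), k))
      }
      if (k == 1) expect_false("connector" %in% spn$nodes$role)
    }
  }
})
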