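test_that("the generator is deterministic in its seed, including emitted files", {
  cfg <- synth_config(n_cells = 60, n_target_genes = 60, n_mutated_genes = 3,
                      n_true_gis = 6, n_decoy_gis = 3, seed = 123)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_gi_data(cfg, dir = d1)
  s2 <- simulate_gi_data(cfg, dir = d2)
  expect_identical(s1$variants, s2$variants)
  expect_identical(unclass(s1$depletion), unclass(s2$depletion))
  expect_identical(s1$reference, s2$reference)
  for (nm in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[nm]]), readLines(s2$paths[[nm]]))
  }
  # a different seed changes the data
  s3 <- simulate_gi_data(synth_config(n_cells = 60, n_target_genes = 60,
                                      n_mutated_genes = 3, n_true_gis = 6,
                                      n_decoy_gis = 3, seed = 124))
  expect_false(identical(unclass(s1$depletion), unclass(s3$depletion)))
})

test_that("emitted files parse through the readers back to the in-memory objects", {
  cfg <- synth_config(n_cells = 50, n_target_genes = 40, n_mutated_genes = 3,
                      n_true_gis = 6, n_decoy_gis = 3, seed = 9)
  dir <- withr::local_tempdir()
  sim <- simulate_gi_data(cfg, dir = dir)
  vt <- read_variant_table(sim$paths$variants)
  expect_equal(vt$gene, sim$variants$gene)
  # depletion is written cells x genes, expression genes x cells: both
  # auto-detect and agree with explicit orientation
  dep <- read_score_matrix(sim$paths$depletion, role = "depletion")
  dep_x <- read_score_matrix(sim$paths$depletion, role = "depletion",
                             orientation = "cells_by_genes")
  expect_identical(unclass(dep), unclass(dep_x))
  expect_equal(dep[rownames(sim$depletion), colnames(sim$depletion)],
               unclass(sim$depletion), tolerance = 1e-12,
               ignore_attr = TRUE)
  expr <- read_score_matrix(sim$paths$expression, role = "expression")
  expect_equal(expr[rownames(sim$expression), colnames(sim$expression)],
               unclass(sim$expression), tolerance = 1e-12,
               ignore_attr = TRUE)
  suppressMessages(net <- load_network(sim$paths$network, directed = FALSE))
  expect_equal(igraph::ecount(net), nrow(sim$network_edges))
  ref <- load_reference_pairs(sim$paths$reference)
  expect_setequal(as.character(ref), sim$reference)
})

test_that("planted mutated genes always pass the recurrence filter", {
  for (s in 1:5) {
    sim <- simulate_gi_data(synth_config(n_cells = 80, n_target_genes = 50,
                                         n_mutated_genes = 4, n_true_gis = 8,
                                         n_decoy_gis = 2, seed = s))
    mut <- suppressMessages(call_functional_mutations(sim$variants))
    rec <- select_recurrent_genes(mut, theta = 0.03)
    expect_true(all(sim$truth$genes$mutated %in% rec))
    # mutation matrix matches the planted mutant cells exactly
    for (q in sim$truth$genes$mutated) {
      expect_setequal(colnames(mut)[mut[q, ] == 1],
                      sim$truth$mutant_cells[[q]])
    }
  }
})

test_that("planted network geometry: true SPs adjacent, decoys at distance >= 3", {
  sim <- simulate_gi_data(synth_config(seed = 31))
  g <- sim$network
  tg <- sim$truth$true_gis
  for (q in unique(tg$mutated_gene)) {
    sps <- tg$target_gene[tg$mutated_gene == q]
    if (length(sps) < 2) next
    D <- igraph::distances(g, v = sps, to = sps)
    expect_true(all(D[upper.tri(D)] <= 1))
  }
  all_sps <- unique(c(tg$target_gene, sim$truth$decoy_gis$target_gene))
  for (d in sim$truth$decoy_gis$target_gene) {
    others <- setdiff(all_sps, d)
    D <- igraph::distances(g, v = d, to = others)
    expect_true(all(D >= 3))
  }
})

test_that("two strong planted interactions are recovered end to end", {
  cfg <- synth_config(n_cells = 200, n_target_genes = 60,
                      n_mutated_genes = 2, n_true_gis = 2, n_decoy_gis = 0,
                      mutation_rate = 0.1, noise_sd = 0.2, effect_size = 1,
                      seed = 77)
  sim <- simulate_gi_data(cfg)
  # oracle first: the planted group difference is overwhelming by t-test
  for (i in 1:2) {
    k <- sim$truth$true_gis$target_gene[i]
    mc <- sim$truth$mutant_cells[[sim$truth$true_gis$mutated_gene[i]]]
    wt <- setdiff(colnames(sim$depletion), mc)
    expect_lt(t.test(sim$depletion[k, mc], sim$depletion[k, wt])$p.value,
              1e-10)
  }
  mut <- suppressMessages(call_functional_mutations(sim$variants))
  rec <- select_recurrent_genes(mut)
  gi <- characterize_gis(sim$depletion, mut, rec,
                         expression = sim$expression)
  found <- paste(gi$mutated_gene, gi$target_gene)
  planted <- paste(sim$truth$true_gis$mutated_gene,
                   sim$truth$true_gis$target_gene)
  expect_true(all(planted %in% found))
  expect_true(all(gi$direction[found %in% planted] == "sensitive"))
})

test_that("a null generator configuration yields (almost) no interactions", {
  cfg <- synth_config(n_cells = 150, n_target_genes = 100,
                      n_mutated_genes = 4, n_true_gis = 4, n_decoy_gis = 0,
                      effect_size = 0, seed = 5)
  sim <- simulate_gi_data(cfg)
  mut <- suppressMessages(call_functional_mutations(sim$variants))
  rec <- select_recurrent_genes(mut)
  gi <- characterize_gis(sim$depletion, mut, rec,
                         expression = sim$expression)
  expect_lte(nrow(gi), 2L)
})

test_that("the confounded fixture behaves like an expression artifact", {
  sim <- make_fig2b_confound(synth_config(n_cells = 100,
                                          n_target_genes = 60,
                                          n_mutated_genes = 3,
                                          n_true_gis = 3, n_decoy_gis = 0,
                                          seed = 42))
  q <- sim$confound$mutated_gene
  k <- sim$confound$target_gene
  mc <- sim$truth$mutant_cells[[q]]
  # construction: the partner is nonexpressed exactly in the mutant cells
  expect_true(all(sim$expression[k, mc] == 0))
  expect_true(all(sim$expression[k, setdiff(colnames(sim$expression),
                                            mc)] > 0))
  mut <- suppressMessages(call_functional_mutations(sim$variants))
  rec <- select_recurrent_genes(mut)
  without <- characterize_gis(sim$depletion, mut, rec,
                              config = gi_test_config(exclusion = FALSE))
  with_ex <- characterize_gis(sim$depletion, mut, rec,
                              expression = sim$expression,
                              config = gi_test_config(exclusion = TRUE))
  key <- paste(q, k)
  expect_true(key %in% paste(without$mutated_gene, without$target_gene))
  expect_false(key %in% paste(with_ex$mutated_gene, with_ex$target_gene))
  # flipping the partner's expression to positive makes masking a no-op
  expr_pos <- unclass(sim$expression)
  expr_pos[k, ] <- 5
  with_pos <- characterize_gis(sim$depletion, mut, rec,
                               expression = score_matrix(expr_pos,
                                                         "expression"),
                               config = gi_test_config(exclusion = TRUE))
  expect_true(key %in% paste(with_pos$mutated_gene, with_pos$target_gene))
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synth_config(n_target_genes = 10, n_true_gis = 20),
               "planted structure")
  expect_error(synth_config(mutation_rate = 0), "mutation_rate")
})
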