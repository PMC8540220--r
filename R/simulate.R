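# Seeded synthetic-data generator: emits every pipeline input (variant
# table, depletion and expression matrices, network edge list, reference
# pair set) with a planted ground truth, in the exact dialects the readers
# accept.

#' Configuration of the synthetic screen generator
#'
#' Defaults describe a desk-scale screen: 200 cell lines, 10 recurrently
#' mutated genes at mutation frequency 0.1, 500 screened genes (5,000 tested
#' pairs), Gaussian depletion noise sd 0.2 with planted mean shifts of 1.0 in
#' mutant cells, a 16% nonexpressed fraction of expression entries, and a
#' network in which each mutated gene's true synthetic partners form a
#' clique while decoy partners sit in their own far-away components.
#'
#' @param n_cells number of cell lines.
#' @param n_target_genes number of loss-of-function screened genes.
#' @param n_mutated_genes number of recurrently mutated genes Q.
#' @param mutation_rate per-cell functional-mutation probability per mutated
#'   gene (frequencies are forced above `recurrence_threshold`).
#' @param noise_sd depletion-score noise standard deviation.
#' @param effect_size planted depletion mean shift in mutant cells
#'   (subtracted for sensitive, added for resistant interactions).
#' @param n_true_gis planted true interactions (spread round-robin over the
#'   mutated genes; each mutated gene's true partners are made mutually
#'   adjacent in the network and enter the reference set).
#' @param n_decoy_gis planted decoy interactions: a real depletion shift, so
#'   the screen finds them, but the partner gene is network-isolated from
#'   every other partner (its own component, hence distance >= 3) and absent
#'   from the reference set.
#' @param true_direction direction of planted true GIs (`"sensitive"` by
#'   default; decoys are always sensitive).
#' @param nonexpressed_fraction fraction of expression entries set to exact
#'   zero at random.
#' @param n_always_nonexpressed filler genes nonexpressed in every cell.
#' @param n_confound_pairs planted expression-confounded pairs: the partner's
#'   depletion shift lives entirely in mutant cells where the partner is
#'   nonexpressed, so the exclusion procedure erases the signal.
#' @param background_edge_prob edge probability among filler network nodes
#'   (true partners and decoys are kept out of the background so planted
#'   distances are exact).
#' @param reference_truth_fraction fraction of planted true pairs included in
#'   the reference set.
#' @param reference_noise_pairs extra random reference pairs (not planted,
#'   not decoys).
#' @param noise_df if finite, draw depletion noise from a scaled Student-t
#'   with this many degrees of freedom instead of a Gaussian.
#' @param recurrence_threshold the recurrence fraction every planted mutated
#'   gene must exceed.
#' @param seed integer seed fixing all randomness end-to-end.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_cells = 200L, n_target_genes = 500L,
                         n_mutated_genes = 10L, mutation_rate = 0.1,
                         noise_sd = 0.2, effect_size = 1.0,
                         n_true_gis = 20L, n_decoy_gis = 10L,
                         true_direction = c("sensitive", "resistant"),
                         nonexpressed_fraction = 0.16,
                         n_always_nonexpressed = 5L,
                         n_confound_pairs = 0L,
                         background_edge_prob = 0.02,
                         reference_truth_fraction = 1.0,
                         reference_noise_pairs = 50L,
                         noise_df = Inf,
                         recurrence_threshold = 0.03,
                         seed = 1L) {
  true_direction <- match.arg(true_direction)
  cfg <- list(n_cells = as.integer(n_cells),
              n_target_genes = as.integer(n_target_genes),
              n_mutated_genes = as.integer(n_mutated_genes),
              mutation_rate = mutation_rate, noise_sd = noise_sd,
              effect_size = effect_size,
              n_true_gis = as.integer(n_true_gis),
              n_decoy_gis = as.integer(n_decoy_gis),
              true_direction = true_direction,
              nonexpressed_fraction = nonexpressed_fraction,
              n_always_nonexpressed = as.integer(n_always_nonexpressed),
              n_confound_pairs = as.integer(n_confound_pairs),
              background_edge_prob = background_edge_prob,
              reference_truth_fraction = reference_truth_fraction,
              reference_noise_pairs = as.integer(reference_noise_pairs),
              noise_df = noise_df,
              recurrence_threshold = recurrence_threshold,
              seed = as.integer(seed))
  stopifnot(cfg$mutation_rate > 0, cfg$mutation_rate < 1,
            cfg$noise_sd > 0,
            cfg$nonexpressed_fraction >= 0, cfg$nonexpressed_fraction < 1,
            cfg$n_cells >= 10L, cfg$n_mutated_genes >= 1L)
  n_special <- cfg$n_true_gis + cfg$n_decoy_gis + cfg$n_confound_pairs +
    cfg$n_always_nonexpressed
  if (n_special > cfg$n_target_genes) {
    stop("not enough target genes for the planted structure (need at least ",
         n_special, ")", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic screen with planted ground truth
#'
#' Emulates the five pipeline inputs: a per-event variant table, a depletion
#' matrix (Gaussian baseline, planted mean shifts in mutant cells), an
#' expression matrix with exact zeros, a gene network whose planted true
#' partners are mutually adjacent while decoys are isolated, and a reference
#' pair set overlapping the planted truth. With `dir` set, files are written
#' in DepMap-compatible dialects: the variant table as CSV with
#' `"SYMBOL (id)"` gene labels, the depletion matrix cells-by-genes (Achilles
#' style) and the expression matrix genes-by-cells, exercising both
#' orientations of [read_score_matrix()].
#'
#' @param config a [synth_config()].
#' @param dir optional output directory for the on-disk fixture.
#' @return list with in-memory canonical objects — `variants`, `depletion`,
#'   `expression`, `network` (igraph), `network_edges`, `reference`
#'   (canonical pair keys), `truth` (planted truth: `true_gis`, `decoy_gis`,
#'   `confound_pairs` data.frames, `mutant_cells` list, `genes`), and
#'   `paths` when `dir` was given.
#' @export
simulate_gi_data <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, simulate_gi_data_impl(config, dir))
}

simulate_gi_data_impl <- function(cfg, dir) {
  cells <- sprintf("ACH-%06d", seq_len(cfg$n_cells))
  q_genes <- sprintf("QG%02d", seq_len(cfg$n_mutated_genes))
  k_genes <- sprintf("TG%04d", seq_len(cfg$n_target_genes))

  # carve special roles out of the target gene pool, disjointly
  pool <- k_genes
  take <- function(n) {
    if (n == 0L) return(character(0))
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  true_k <- take(cfg$n_true_gis)
  decoy_k <- take(cfg$n_decoy_gis)
  confound_k <- take(cfg$n_confound_pairs)
  never_expr <- take(cfg$n_always_nonexpressed)
  filler <- pool

  assign_qs <- function(ks) {
    if (length(ks) == 0L) return(character(0))
    q_genes[((seq_along(ks) - 1L) %% cfg$n_mutated_genes) + 1L]
  }
  true_gis <- data.frame(
    mutated_gene = assign_qs(true_k), target_gene = true_k,
    direction = rep(cfg$true_direction, length(true_k)),
    stringsAsFactors = FALSE)
  decoy_gis <- data.frame(
    mutated_gene = assign_qs(decoy_k), target_gene = decoy_k,
    direction = rep("sensitive", length(decoy_k)),
    stringsAsFactors = FALSE)
  confound_pairs <- data.frame(
    mutated_gene = assign_qs(confound_k), target_gene = confound_k,
    direction = rep("sensitive", length(confound_k)),
    stringsAsFactors = FALSE)

  # mutant cell sets: Bernoulli(mutation_rate), forced above the recurrence
  # threshold so every planted mutated gene survives the recurrence filter
  min_mut <- floor(cfg$recurrence_threshold * cfg$n_cells) + 1L
  mutant_cells <- lapply(q_genes, function(q) {
    hit <- which(stats::runif(cfg$n_cells) < cfg$mutation_rate)
    if (length(hit) < min_mut) {
      extra <- sample(setdiff(seq_len(cfg$n_cells), hit),
                      min_mut - length(hit))
      hit <- sort(c(hit, extra))
    }
    cells[hit]
  })
  names(mutant_cells) <- q_genes

  # variant table: one deleterious event per mutant cell (classification
  # drawn from the MAF-style spellings), benign records as negatives, and a
  # couple of sub-threshold background genes to exercise the recurrence filter
  deleterious_spellings <- c("Missense_Mutation", "Nonsense_Mutation",
                             "Frame_Shift_Del", "Frame_Shift_Ins",
                             "Splice_Site", "In_Frame_Del",
                             "Nonstop_Mutation", "Stop_Codon_Del")
  rows <- lapply(q_genes, function(q) {
    mc <- mutant_cells[[q]]
    data.frame(cell_id = mc, gene = q,
               variant_classification = sample(deleterious_spellings,
                                               length(mc), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  # every profiled cell line carries at least one (benign) event, as in real
  # mutation profiles, so the cell universe covers the whole panel and
  # record-free genes are genuinely wild type
  benign <- data.frame(cell_id = cells,
                       gene = sample(c(q_genes, utils::head(filler, 20L)),
                                     cfg$n_cells, replace = TRUE),
                       variant_classification = sample(c("Silent", "3'UTR",
                                                         "Intron"),
                                                       cfg$n_cells,
                                                       replace = TRUE),
                       stringsAsFactors = FALSE)
  sub_threshold <- utils::head(filler, 2L)
  background <- data.frame(
    cell_id = sample(cells, 2L * length(sub_threshold), replace = FALSE),
    gene = rep(sub_threshold, each = 2L),
    variant_classification = "Missense_Mutation",
    stringsAsFactors = FALSE)
  variants <- do.call(rbind, c(rows, list(benign, background)))
  rownames(variants) <- NULL

  # depletion: noise baseline plus planted shifts in mutant cells
  n_k <- length(k_genes)
  noise <- if (is.finite(cfg$noise_df)) {
    scale <- cfg$noise_sd / sqrt(cfg$noise_df / (cfg$noise_df - 2))
    matrix(stats::rt(n_k * cfg$n_cells, df = cfg$noise_df) * scale,
           nrow = n_k)
  } else {
    matrix(stats::rnorm(n_k * cfg$n_cells, 0, cfg$noise_sd), nrow = n_k)
  }
  depletion <- noise
  dimnames(depletion) <- list(k_genes, cells)
  plant <- function(df) {
    for (i in seq_len(nrow(df))) {
      shift <- if (df$direction[i] == "sensitive") -cfg$effect_size
               else cfg$effect_size
      depletion[df$target_gene[i], mutant_cells[[df$mutated_gene[i]]]] <<-
        depletion[df$target_gene[i], mutant_cells[[df$mutated_gene[i]]]] +
        shift
    }
  }
  plant(true_gis)
  plant(decoy_gis)
  plant(confound_pairs)
  depletion <- score_matrix(depletion, "depletion")

  # expression: per-gene positive level, random exact zeros, designated
  # always-nonexpressed genes, and confounded partners nonexpressed exactly
  # in the mutant cells
  level <- stats::runif(n_k, 1, 8)
  expression <- matrix(pmax(0.1, level +
                              stats::rnorm(n_k * cfg$n_cells, 0, 0.5)),
                       nrow = n_k, dimnames = list(k_genes, cells))
  if (cfg$nonexpressed_fraction > 0) {
    zero <- stats::runif(n_k * cfg$n_cells) < cfg$nonexpressed_fraction
    expression[zero] <- 0
  }
  expression[never_expr, ] <- 0
  for (i in seq_len(nrow(confound_pairs))) {
    k <- confound_pairs$target_gene[i]
    mc <- mutant_cells[[confound_pairs$mutated_gene[i]]]
    expression[k, ] <- pmax(expression[k, ], 1)
    expression[k, mc] <- 0
  }
  expression <- score_matrix(expression, "expression")

  # network: per-Q cliques over true partners, decoys in private two-node
  # components, background edges among fillers only
  edges <- list()
  for (q in q_genes) {
    sps <- true_gis$target_gene[true_gis$mutated_gene == q]
    if (length(sps) >= 2L) {
      cmb <- utils::combn(sort(sps), 2L)
      edges[[length(edges) + 1L]] <- data.frame(from = cmb[1L, ],
                                                to = cmb[2L, ],
                                                stringsAsFactors = FALSE)
    }
  }
  if (length(decoy_k)) {
    edges[[length(edges) + 1L]] <- data.frame(
      from = decoy_k, to = paste0("NB_", decoy_k), stringsAsFactors = FALSE)
  }
  bg_nodes <- c(filler, confound_k)
  if (length(bg_nodes) >= 2L && cfg$background_edge_prob > 0) {
    cmb <- utils::combn(bg_nodes, 2L)
    pick <- stats::runif(ncol(cmb)) < cfg$background_edge_prob
    if (any(pick)) {
      edges[[length(edges) + 1L]] <- data.frame(from = cmb[1L, pick],
                                                to = cmb[2L, pick],
                                                stringsAsFactors = FALSE)
    }
  }
  network_edges <- unique(do.call(rbind, edges))
  rownames(network_edges) <- NULL
  network <- igraph::graph_from_data_frame(network_edges, directed = FALSE)

  # reference set: planted truth (sampled at the truth fraction) plus noise
  truth_keys <- reference_pairs(true_gis[, c("mutated_gene", "target_gene")])
  n_keep <- round(cfg$reference_truth_fraction * length(truth_keys))
  kept <- if (n_keep >= length(truth_keys)) truth_keys
          else sample(truth_keys, n_keep)
  decoy_keys <- reference_pairs(decoy_gis[, c("mutated_gene", "target_gene")])
  all_genes <- c(q_genes, k_genes)
  noise_keys <- character(0)
  while (length(noise_keys) < cfg$reference_noise_pairs) {
    a <- sample(all_genes, cfg$reference_noise_pairs, replace = TRUE)
    b <- sample(all_genes, cfg$reference_noise_pairs, replace = TRUE)
    cand <- unique(canonical_pairs(a[a != b], b[a != b]))
    cand <- setdiff(cand, c(truth_keys, decoy_keys, noise_keys))
    noise_keys <- c(noise_keys,
                    utils::head(cand,
                                cfg$reference_noise_pairs - length(noise_keys)))
  }
  reference <- unique(c(kept, noise_keys))

  truth <- list(true_gis = true_gis, decoy_gis = decoy_gis,
                confound_pairs = confound_pairs,
                mutant_cells = mutant_cells,
                always_nonexpressed = never_expr,
                genes = list(mutated = q_genes, targets = k_genes,
                             filler = filler))

  out <- list(variants = variants, depletion = depletion,
              expression = expression, network = network,
              network_edges = network_edges, reference = reference,
              truth = truth, config = cfg)
  if (!is.null(dir)) out$paths <- write_synth_files(out, dir)
  out
}

# On-disk fixture in the dialects the readers accept.
write_synth_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    variants = file.path(dir, "variants.csv"),
    depletion = file.path(dir, "depletion.csv"),
    expression = file.path(dir, "expression.csv"),
    network = file.path(dir, "network.tsv"),
    reference = file.path(dir, "reference.tsv"),
    truth = file.path(dir, "truth.json")
  )
  fake_entrez <- function(genes) {
    sprintf("%s (%d)", genes, 10000L + as.integer(factor(genes)))
  }
  vr <- data.frame(DepMap_ID = sim$variants$cell_id,
                   Hugo_Symbol = fake_entrez(sim$variants$gene),
                   Variant_Classification = sim$variants$variant_classification)
  utils::write.csv(vr, paths$variants, row.names = FALSE, quote = FALSE)

  dep <- t(unclass(sim$depletion))                      # cells x genes
  colnames(dep) <- fake_entrez(colnames(dep))
  utils::write.csv(data.frame(DepMap_ID = rownames(dep), dep,
                              check.names = FALSE),
                   paths$depletion, row.names = FALSE, quote = FALSE)

  expr <- unclass(sim$expression)                       # genes x cells
  utils::write.csv(data.frame(gene = fake_entrez(rownames(expr)), expr,
                              check.names = FALSE),
                   paths$expression, row.names = FALSE, quote = FALSE)

  utils::write.table(rbind(c("source", "target"),
                           as.matrix(sim$network_edges)),
                     paths$network, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ref <- attr_pairs(sim$reference)
  utils::write.table(ref, paths$reference, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  jsonlite::write_json(list(true_gis = sim$truth$true_gis,
                            decoy_gis = sim$truth$decoy_gis,
                            confound_pairs = sim$truth$confound_pairs,
                            mutant_cells = sim$truth$mutant_cells,
                            always_nonexpressed = sim$truth$always_nonexpressed),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE)
  paths
}

attr_pairs <- function(keys) {
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(gene1 = vapply(parts, `[[`, "", 1L),
             gene2 = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Construct an expression-confounded fixture
#'
#' Produces a screen containing at least one planted pair whose depletion
#' difference is carried entirely by mutant cells in which the partner gene
#' is nonexpressed. Without the exclusion procedure the pair is reported as
#' a sensitive GI; with exclusion its case group is fully masked, the test is
#' skipped, and the pair disappears — the signature of an expression
#' artifact.
#'
#' @param config a [synth_config()]; `n_confound_pairs` is forced to at
#'   least 1.
#' @param dir optional output directory, see [simulate_gi_data()].
#' @return as [simulate_gi_data()], plus `confound` (the first planted
#'   confounded pair).
#' @export
make_fig2b_confound <- function(config = synth_config(), dir = NULL) {
  cfg <- unclass(config)
  cfg$n_confound_pairs <- max(1L, cfg$n_confound_pairs)
  config <- do.call(synth_config, cfg[setdiff(names(cfg), character(0))])
  sim <- simulate_gi_data(config, dir)
  sim$confound <- sim$truth$confound_pairs[1L, ]
  sim
}
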