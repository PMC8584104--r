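test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(de_fraction = 1.2), "proportion")
  expect_error(sim_config(n_genes = 10.5), "integer")
  expect_error(sim_config(group_sizes = c(1, 14)), "at least 2")
  expect_error(sim_config(within_block_overlap = 0.8,
                          between_block_overlap = 0.3), "sum above 1")
  expect_error(sim_config(evidence_channel_probs = c(a = 2, b = 0, c = 0,
                                                     d = 0, e = 0, f = 0)),
               "proportion")
})

test_that("every generator is a pure function of its configuration", {
  cfg <- small_config(seed = 5)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$collection, s2$collection)
  expect_identical(s1$evidence, s2$evidence)
  expect_identical(s1$ppi_edges, s2$ppi_edges)
  expect_identical(s1$truth, s2$truth)
})

test_that("the Poisson branch and NB moments match the stated law", {
  # dispersion 0: Poisson limit; 10,000 draws at mu = 50
  cfg <- sim_config(n_genes = 10000, baseline_mean_log_mu = log(50),
                    baseline_mean_log_sigma = 0, dispersion = 0,
                    libsize_log_sigma = 0, de_fraction = 0, seed = 9)
  sim <- simulate_counts(cfg)
  expect_lt(abs(mean(sim$counts[, 1]) - 50), 3 * sqrt(50 / 10000))

  # NB: variance close to mu + alpha mu^2 across many genes
  cfg2 <- sim_config(n_genes = 4000, baseline_mean_log_mu = log(100),
                     baseline_mean_log_sigma = 0, dispersion = 0.2,
                     libsize_log_sigma = 0, de_fraction = 0, seed = 10)
  counts <- simulate_counts(cfg2)$counts
  vr <- apply(counts, 1, var)
  expect_equal(mean(vr), 100 + 0.2 * 100^2, tolerance = 0.05)
})

test_that("planting no effects leaves the truth empty", {
  sim <- simulate_counts(small_config(de_fraction = 0))
  expect_length(sim$truth$de_genes, 0)
})

test_that("the sample sheet mirrors the emulated specimen design", {
  sim <- simulate_counts(sim_config(n_genes = 50, seed = 2,
                                    baseline_mean_log_mu = 3))
  expect_equal(table(sim$samples$group)[["malignant"]], 10)
  expect_equal(table(sim$samples$group)[["nonmalignant"]], 14)
  expect_equal(sum(sim$samples$specimen_type == "FNA" &
                     sim$samples$group == "malignant"), 1)
  expect_equal(sum(sim$samples$specimen_type == "FNA" &
                     sim$samples$group == "nonmalignant"), 5)
})

test_that("degenerate overlap parameters give identical or disjoint pathways", {
  cfg <- sim_config(n_genes = 1000, pathways_per_block = 3,
                    n_superpathway_blocks = 2, pathway_size = 20,
                    within_block_overlap = 1, between_block_overlap = 0,
                    seed = 3)
  pw <- simulate_pathways(cfg, sprintf("u%04d", 1:1000))
  blocks <- split(names(pw$collection), pw$block_of_pathway)
  for (b in blocks) {
    expect_identical(pw$collection[[b[1]]], pw$collection[[b[2]]])
  }
  expect_equal(overlap_coefficient(pw$collection[[blocks[[1]][1]]],
                                   pw$collection[[blocks[[2]][1]]]), 0)
})

test_that("pathway collections round-trip through GMT unchanged", {
  cfg <- small_config(seed = 4)
  pw <- simulate_pathways(cfg, sprintf("u%04d", 1:600))
  path <- tempfile(fileext = ".gmt")
  write_gmt(pw$collection, path)
  back <- read_gmt(path)
  expect_identical(names(back), names(pw$collection))
  expect_identical(lapply(back, identity)[names(back)],
                   pw$collection[names(back)])
})

test_that("a too-small universe is rejected", {
  cfg <- sim_config(n_genes = 100, seed = 1)
  expect_error(simulate_pathways(cfg, sprintf("u%03d", 1:100)), "smaller")
})

test_that("the planted partition maximizes within-cluster overlap", {
  cfg <- sim_config(n_genes = 2000, n_superpathway_blocks = 2,
                    pathways_per_block = 3, pathway_size = 20,
                    within_block_overlap = 0.8, between_block_overlap = 0.05,
                    seed = 6)
  pw <- simulate_pathways(cfg, sprintf("u%04d", 1:2000))
  oc <- overlap_matrix(pw$collection)
  ids <- names(pw$collection)
  mean_within <- function(groups) {
    mean(unlist(lapply(groups, function(g) {
      oc[g, g][lower.tri(diag(length(g)))]
    })))
  }
  planted <- split(ids, pw$block_of_pathway)
  best <- -Inf; best_is_planted <- FALSE
  for (trip in utils::combn(ids, 3, simplify = FALSE)) {
    part <- list(trip, setdiff(ids, trip))
    score <- mean_within(part)
    if (score > best) {
      best <- score
      best_is_planted <- setequal(part[[1]], planted[[1]]) ||
        setequal(part[[1]], planted[[2]])
    }
  }
  expect_true(best_is_planted)
  expect_equal(best, mean_within(planted))
})

test_that("evidence flags have the stated marginal behavior", {
  cfg0 <- small_config(evidence_channel_probs = setNames(rep(0, 6),
    c("hpa_prostate", "pca_pathway", "oncogene_tk", "literature",
      "assay", "druggable")))
  ev0 <- simulate_evidence(cfg0, sprintf("g%04d", 1:500))
  expect_equal(sum(as.matrix(ev0[-1])), 0)

  cfg1 <- small_config(evidence_channel_probs = setNames(rep(1, 6),
    c("hpa_prostate", "pca_pathway", "oncogene_tk", "literature",
      "assay", "druggable")))
  ev1 <- simulate_evidence(cfg1, sprintf("g%04d", 1:500))
  expect_equal(sum(as.matrix(ev1[-1])), 500 * 6)

  # p = 0.1 on 5000 genes: count inside the 99% binomial interval
  cfgp <- sim_config(n_genes = 5000, seed = 12,
                     evidence_channel_probs = setNames(rep(0.1, 6),
    c("hpa_prostate", "pca_pathway", "oncogene_tk", "literature",
      "assay", "druggable")))
  evp <- simulate_evidence(cfgp, sprintf("g%05d", 1:5000))
  count <- sum(evp$literature)
  expect_gte(count, qbinom(0.005, 5000, 0.1))
  expect_lte(count, qbinom(0.995, 5000, 0.1))
})

test_that("correlated evidence channels preserve marginals but co-occur more", {
  probs <- setNames(rep(0.2, 6), c("hpa_prostate", "pca_pathway",
                                   "oncogene_tk", "literature", "assay",
                                   "druggable"))
  genes <- sprintf("g%04d", 1:4000)
  ind <- simulate_evidence(sim_config(n_genes = 4000, seed = 13,
                                      evidence_channel_probs = probs), genes)
  cor <- simulate_evidence(sim_config(n_genes = 4000, seed = 13,
                                      evidence_channel_probs = probs,
                                      evidence_correlation = 0.8), genes)
  expect_equal(mean(as.matrix(cor[-1])), 0.2, tolerance = 0.05)
  # among flagged genes, correlation concentrates flags on fewer genes, so
  # the multi-channel share of the flagged set grows
  multi_share <- function(ev) {
    k <- rowSums(as.matrix(ev[-1]))
    sum(k >= 2) / sum(k >= 1)
  }
  expect_gt(multi_share(cor), multi_share(ind))
})

test_that("PPI generation honours structural invariants", {
  cfg <- small_config(seed = 14)
  universe <- sprintf("g%04d", 1:300)
  coll <- list(a = universe[1:30], b = universe[31:60])
  ppi <- simulate_ppi(cfg, universe, coll)
  e <- ppi$edges
  expect_false(any(e$gene_a == e$gene_b))
  key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  expect_false(any(duplicated(key)))
  expect_true(all(e$confidence >= 0 & e$confidence <= 1))
  expect_length(ppi$hub_genes, cfg$n_hubs)

  none <- simulate_ppi(small_config(ppi_within_density = 0,
                                    ppi_between_density = 0, n_hubs = 0),
                       universe, coll)
  expect_equal(nrow(none$edges), 0)
})

test_that("planted hubs exceed the network hub rule in replicates", {
  hits <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_genes = 400, pathways_per_block = 2, seed = 100 + r)
    universe <- sprintf("g%04d", 1:400)
    coll <- simulate_pathways(cfg, universe)$collection
    ppi <- simulate_ppi(cfg, universe, coll)
    net <- build_network(ppi$edges, universe)
    if (all(ppi$hub_genes %in% net$hubs)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("the ortholog map is mostly one-to-one with planted one-to-many", {
  cfg <- sim_config(n_genes = 2000, seed = 15)
  genes <- sprintf("g%04d", 1:2000)
  map <- simulate_ortholog_map(cfg, genes)
  expect_true(all(map$source_gene %in% genes))
  expect_false(anyDuplicated(map[c("source_gene", "target_gene")]) > 0)
  per_source <- table(map$source_gene)
  expect_gt(sum(per_source == 2), 0)       # some one-to-many
  expect_gt(mean(per_source == 1), 0.9)    # but mostly one-to-one
})
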