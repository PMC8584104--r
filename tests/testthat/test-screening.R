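test_that("expression percentile filter uses strict interpolation thresholds", {
  # group medians 1..10: 40th percentile threshold is 4.6
  tab <- make_deg_table(sprintf("g%02d", 1:10), med_mal = 1:10, med_non = 0)
  pass <- expression_percentile_filter(tab, 40)
  expect_equal(which(pass), 5:10)

  # all genes identical: threshold equals the value, strict > passes nothing
  flat <- make_deg_table(sprintf("g%02d", 1:8), med_mal = 3, med_non = 3)
  expect_false(any(expression_percentile_filter(flat, 40)))

  # OR across groups: above threshold in one group only is enough
  mixed <- make_deg_table(c("lo", "hi_non"), med_mal = c(1, 1),
                          med_non = c(1, 100))
  mixed$median_norm_malignant <- c(1, 1)
  mixed$median_norm_nonmalignant <- c(1, 100)
  expect_equal(expression_percentile_filter(mixed, 40), c(FALSE, TRUE))
})

test_that("the S tier is the conjunction of its four criteria", {
  tab <- make_deg_table(sprintf("g%d", 1:8),
                        log2fc = c(2, -2, 5, 1.9, 2.5, -3, 4, 2.2),
                        fdr = c(rep(1e-9, 7), 0.5),
                        med_mal = c(100, 90, 80, 70, 0, 60, 50, 40),
                        med_non = 0)
  # 40th percentile of the malignant medians is 58: g1-g4 and g6 pass
  sp_genes <- sprintf("g%d", c(1, 2, 3, 4, 5, 7, 8))  # g6 not in superpathway
  res <- screen_deg_s(tab, sp_genes)
  # brute-force conjunction
  pass <- expression_percentile_filter(tab, 40)
  want <- tab$is_deg & abs(tab$log2fc) >= 2 & pass &
    tab$gene_id %in% sp_genes
  expect_equal(res$is_deg_s, want)
  expect_true(res$is_deg_s[1])            # log2fc exactly 2 counts (inclusive)
  expect_false(res$is_deg_s[6])           # |lfc| = 3 but outside superpathways
  expect_false(res$is_deg_s[8])           # not a DEG

  strict <- screen_deg_s(tab, sp_genes,
                         screen_config(fc_inclusive = FALSE))
  expect_false(strict$is_deg_s[1])
})

test_that("the D tier requires differential expression plus any flag", {
  tab <- make_deg_table(c("d1", "d2", "n1"), fdr = c(1e-9, 1e-9, 0.9))
  cat <- data.frame(gene_id = c("d1", "n1"),
                    hpa_prostate = c(0, 1), pca_pathway = c(1, 1),
                    oncogene_tk = c(0, 1), literature = c(0, 1),
                    assay = c(0, 1), druggable = c(0, 1))
  res <- screen_deg_d(tab, cat)
  expect_equal(res$is_deg_d, c(TRUE, FALSE, FALSE))
  # d2 absent from catalog -> all flags default to false
  expect_false(any(unlist(res[res$gene_id == "d2",
                              attr(res, "channels")])))
})

test_that("tier intersection equals the set-operation oracle", {
  set.seed(23)
  for (i in 1:20) {
    n <- 30
    tab <- make_deg_table(sprintf("g%02d", 1:n),
                          log2fc = runif(n, -5, 5),
                          fdr = sample(c(1e-9, 0.5), n, replace = TRUE),
                          med_mal = runif(n, 0, 100), med_non = 0)
    tab$median_norm_malignant <- runif(n, 0, 100)
    sp <- sample(tab$gene_id, 15)
    cat <- data.frame(gene_id = tab$gene_id,
                      hpa_prostate = rbinom(n, 1, 0.2),
                      pca_pathway = rbinom(n, 1, 0.2),
                      oncogene_tk = rbinom(n, 1, 0.2),
                      literature = rbinom(n, 1, 0.3),
                      assay = rbinom(n, 1, 0.1),
                      druggable = rbinom(n, 1, 0.3))
    res <- screen_genes(tab, sp, cat)
    s_set <- res$gene_id[res$is_deg_s]
    d_set <- res$gene_id[res$is_deg_d]
    expect_setequal(res$gene_id[res$is_deg_sd], intersect(s_set, d_set))
    # tier monotonicity
    deg_set <- res$gene_id[res$is_deg]
    expect_true(all(s_set %in% deg_set))
    expect_true(all(d_set %in% deg_set))
  }
})

test_that("disjoint S and D tiers give an empty SD; S within D gives S", {
  tab <- make_deg_table(c("a", "b"), log2fc = c(3, 3), fdr = 1e-9,
                        med_mal = c(10, 20), med_non = 0)
  s1 <- screen_deg_s(tab, "b")   # only b in a superpathway
  cat <- data.frame(gene_id = "a", druggable = 1)
  d1 <- screen_deg_d(tab, cat)   # only a flagged
  sd1 <- intersect_deg_sd(s1, d1)
  expect_false(any(sd1$is_deg_sd))

  cat2 <- data.frame(gene_id = c("a", "b"), druggable = c(1, 1))
  sd2 <- intersect_deg_sd(s1, screen_deg_d(tab, cat2))  # S subset of D
  expect_equal(sd2$is_deg_sd, sd2$is_deg_s)
})

test_that("raising the fold-change threshold never grows the S tier", {
  set.seed(29)
  tab <- make_deg_table(sprintf("g%02d", 1:40),
                        log2fc = runif(40, -6, 6),
                        fdr = sample(c(1e-9, 0.5), 40, replace = TRUE),
                        med_mal = runif(40, 0, 50), med_non = 0)
  tab$median_norm_malignant <- runif(40, 0, 50)
  sp <- tab$gene_id
  sizes <- vapply(c(1, 2, 3, 4, 5), function(fc) {
    sum(screen_deg_s(tab, sp, screen_config(fc_threshold = fc))$is_deg_s)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("UpSet cells are disjoint, exhaustive, and match enumeration", {
  # one gene flagged druggable only
  one <- make_screen_result(data.frame(gene_id = "g1", is_deg = TRUE,
                                       druggable = TRUE, is_deg_d = TRUE))
  u1 <- upset_counts(one)
  expect_equal(nrow(u1), 1)
  expect_true(u1$druggable && !u1$deg_s)
  expect_equal(u1$count, 1L)

  set.seed(31)
  n <- 20
  df <- data.frame(gene_id = sprintf("g%02d", 1:n), is_deg = TRUE)
  channels <- c("hpa_prostate", "pca_pathway", "oncogene_tk",
                "literature", "assay", "druggable")
  for (ch in channels) df[[ch]] <- as.logical(rbinom(n, 1, 0.3))
  df$is_deg_d <- rowSums(as.matrix(df[channels])) > 0
  df$is_deg_s <- as.logical(rbinom(n, 1, 0.4))
  df$is_deg_sd <- df$is_deg_s & df$is_deg_d
  res <- make_screen_result(df)
  u <- upset_counts(res)
  union_n <- sum(df$is_deg_s | df$is_deg_d)
  expect_equal(sum(u$count), union_n)
  # exhaustive 2^7 enumeration oracle
  crit <- c(channels, "deg_s")
  sub <- df[df$is_deg_s | df$is_deg_d, ]
  flags <- cbind(sub[channels], deg_s = sub$is_deg_s)
  for (r in seq_len(nrow(u))) {
    want <- sum(apply(flags, 1, function(row) {
      all(as.logical(row) == as.logical(u[r, crit]))
    }))
    expect_equal(u$count[r], want)
  }
  # disjointness: no two rows share the same combination
  expect_false(anyDuplicated(u[crit]) > 0)
})

test_that("report summary reproduces the printed-share arithmetic", {
  mk <- function(n_deg, n_up, n_strong_up, n_strong_down) {
    lfc <- c(rep(3, n_strong_up), rep(1, n_up - n_strong_up),
             rep(-3, n_strong_down), rep(-1, n_deg - n_up - n_strong_down))
    make_screen_result(data.frame(
      gene_id = sprintf("g%05d", seq_len(n_deg)),
      is_deg = TRUE, log2fc = lfc))
  }
  s <- report_summary(mk(4098, 2454, 1665, 839))
  expect_equal(s$pct_up, 60)
  expect_equal(s$pct_strong_up, 41)

  empty <- make_screen_result(data.frame(gene_id = "g1", is_deg = FALSE))
  s0 <- report_summary(empty)
  expect_equal(s0$n_degs, 0)
  expect_true(is.na(s0$pct_up))
  expect_true(is.na(s0$pct_deg_d))
})

test_that("screen results are invariant to gene order", {
  set.seed(37)
  n <- 25
  tab <- make_deg_table(sprintf("g%02d", 1:n),
                        log2fc = runif(n, -5, 5),
                        fdr = sample(c(1e-9, 0.5), n, replace = TRUE),
                        med_mal = runif(n, 0, 50), med_non = runif(n, 0, 50))
  sp <- sample(tab$gene_id, 10)
  cat <- data.frame(gene_id = tab$gene_id, druggable = rbinom(n, 1, 0.4))
  r1 <- screen_genes(tab, sp, cat)
  perm <- sample(n)
  r2 <- screen_genes(tab[perm, ], sp, cat)
  expect_equal(r2[order(r2$gene_id), "is_deg_s"],
               r1[order(r1$gene_id), "is_deg_s"])
  expect_equal(r2[order(r2$gene_id), "is_deg_sd"],
               r1[order(r1$gene_id), "is_deg_sd"])
})
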