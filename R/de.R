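#' Differential-expression configuration
#'
#' Collects the tuning constants of the differential-expression stage. The
#' defaults implement the study's decision rule: a gene is differentially
#' expressed when its Benjamini-Hochberg adjusted p-value is at most
#' `1e-5` (inclusive).
#'
#' @param fdr_de_threshold FDR cutoff for calling a gene differentially
#'   expressed; the boundary is inclusive.
#' @param dispersion_floor Lower bound for the method-of-moments dispersion
#'   estimate, applied when the sample variance does not exceed the mean.
#' @param pseudo_log_offset Pseudo-count added before the `log2` transform
#'   used for sample ordination.
#' @param lfc_pseudocount Pseudo-count (in normalized-count units) added to
#'   both group means before forming the log2 fold-change, keeping genes
#'   with an all-zero group finite.
#' @return A list of class `de_config`.
#' @export
de_config <- function(fdr_de_threshold = 1e-5,
                      dispersion_floor = 1e-8,
                      pseudo_log_offset = 1,
                      lfc_pseudocount = 0.5) {
  if (fdr_de_threshold <= 0 || fdr_de_threshold >= 1) {
    stopf("'fdr_de_threshold' must lie in (0, 1)")
  }
  check_positive(dispersion_floor, "dispersion_floor")
  check_positive(pseudo_log_offset, "pseudo_log_offset")
  check_positive(lfc_pseudocount, "lfc_pseudocount")
  structure(list(fdr_de_threshold = fdr_de_threshold,
                 dispersion_floor = dispersion_floor,
                 pseudo_log_offset = pseudo_log_offset,
                 lfc_pseudocount = lfc_pseudocount),
            class = "de_config")
}

#' Median-of-ratios size factors
#'
#' Estimates one positive scaling factor per sample so that counts are
#' comparable across sequencing depths. The per-gene reference is the
#' geometric mean across samples, computed over genes with strictly
#' positive counts in every sample; each sample's factor is the median of
#' its count-to-reference ratios over those genes. Genes containing a zero
#' contribute to no sample's median.
#'
#' @param counts Non-negative integer matrix, genes in rows (named),
#'   samples in columns.
#' @return Numeric vector of positive size factors, one per sample.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' estimate_size_factors(m)  # c(1/sqrt(2), sqrt(2))
estimate_size_factors <- function(counts) {
  check_count_matrix(counts)
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    stopf(paste("no gene has positive counts in every sample;",
                "filter low-count genes before normalization"))
  }
  lc <- log(counts[all_pos, , drop = FALSE])
  log_ref <- rowMeans(lc)
  sf <- exp(apply(lc - log_ref, 2, median))
  names(sf) <- colnames(counts)
  sf
}

#' Gene-wise method-of-moments dispersion estimates
#'
#' Estimates the negative-binomial dispersion `alpha` of each gene under
#' the parameterization `variance = mu + alpha * mu^2`, from normalized
#' counts pooled within the two sample groups: the pooled within-group
#' variance `s2` and the overall mean `m` give
#' `alpha = max(floor, (s2 - m) / m^2)`.
#'
#' @inheritParams estimate_size_factors
#' @param size_factors Per-sample size factors, as returned by
#'   [estimate_size_factors()].
#' @param groups Two-level grouping vector aligned with the columns of
#'   `counts`.
#' @param dispersion_floor Lower bound for the estimate.
#' @return Named non-negative numeric vector, one finite value per gene.
#' @export
estimate_dispersions <- function(counts, size_factors, groups,
                                 dispersion_floor = 1e-8) {
  check_count_matrix(counts)
  check_positive(size_factors, "size_factors")
  lv <- unique(as.character(groups))
  if (length(lv) != 2) stopf("'groups' must have exactly two levels")
  norm <- sweep(counts, 2, size_factors, "/")
  i1 <- which(groups == lv[1]); i2 <- which(groups == lv[2])
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  ss <- rowSums((norm[, i1, drop = FALSE] - m1)^2) +
        rowSums((norm[, i2, drop = FALSE] - m2)^2)
  s2 <- ss / (length(i1) + length(i2) - 2)
  m_bar <- rowMeans(norm)
  alpha <- ifelse(m_bar > 0, (s2 - m_bar) / m_bar^2, dispersion_floor)
  alpha <- pmax(dispersion_floor, alpha)
  names(alpha) <- rownames(counts)
  alpha
}

#' Two-group negative-binomial Wald test
#'
#' Tests each gene for a difference in mean normalized expression between
#' the numerator and denominator group of `contrast`. The log2 fold-change
#' is `log2((m_num + eps) / (m_den + eps))` over group means of normalized
#' counts; its standard error comes from the observed Fisher information of
#' the two-group NB log-mean model at the plug-in dispersion, and the Wald
#' statistic is referred to a standard normal. Genes with all-zero counts
#' are reported with `log2fc = 0` and `p_value = 1`.
#'
#' @inheritParams estimate_dispersions
#' @param dispersions Per-gene NB dispersions, as from
#'   [estimate_dispersions()].
#' @param contrast Character pair `(numerator, denominator)` naming the two
#'   group levels; fold-changes are numerator over denominator.
#' @param lfc_pseudocount Pseudo-count added to both group means before the
#'   log-ratio.
#' @return A `data.frame` with one row per gene: `gene_id`, `base_mean`,
#'   `log2fc`, `se`, `wald_stat`, `p_value`, and the per-group median
#'   normalized counts in columns `median_norm_<group>`.
#' @export
nb_wald_test <- function(counts, size_factors, dispersions, groups,
                         contrast = c("malignant", "nonmalignant"),
                         lfc_pseudocount = 0.5) {
  check_count_matrix(counts)
  idx <- group_indices(groups, contrast)
  if (length(idx$num) < 2 || length(idx$den) < 2) {
    stopf("each group needs at least 2 samples (got %d and %d)",
          length(idx$num), length(idx$den))
  }
  f <- size_factors
  norm <- sweep(counts, 2, f, "/")
  m1 <- rowMeans(norm[, idx$num, drop = FALSE])
  m2 <- rowMeans(norm[, idx$den, drop = FALSE])
  eps <- lfc_pseudocount
  lfc <- log2((m1 + eps) / (m2 + eps))

  # Fisher information of log(mu) per group: sum_s f_s*mu / (1 + a*f_s*mu),
  # evaluated at the pseudo-counted group means so all-zero groups stay finite.
  a <- dispersions
  A1 <- outer(m1 + eps, f[idx$num])
  A2 <- outer(m2 + eps, f[idx$den])
  info1 <- rowSums(A1 / (1 + a * A1))
  info2 <- rowSums(A2 / (1 + a * A2))
  se <- sqrt(1 / info1 + 1 / info2) / log(2)
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))

  all_zero <- rowSums(counts) == 0
  lfc[all_zero] <- 0
  z[all_zero] <- 0
  p[all_zero] <- 1
  se[all_zero] <- NA_real_

  med1 <- apply(norm[, idx$num, drop = FALSE], 1, median)
  med2 <- apply(norm[, idx$den, drop = FALSE], 1, median)

  out <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(norm),
                    log2fc = lfc, se = se, wald_stat = z, p_value = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[[paste0("median_norm_", contrast[1])]] <- med1
  out[[paste0("median_norm_", contrast[2])]] <- med2
  attr(out, "contrast") <- contrast
  attr(out, "lfc_pseudocount") <- eps
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Shared multiple-testing routine for every stage of the pipeline
#' (gene-level Wald p-values and pathway-level enrichment p-values alike).
#'
#' @param p Numeric vector of p-values.
#' @return FDR-adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Adds BH-adjusted p-values and the DEG flag to a Wald-test table. The
#' threshold is inclusive: a gene whose FDR equals the threshold is called.
#'
#' @param table Result of [nb_wald_test()].
#' @param config A [de_config()].
#' @return The table with `fdr` and `is_deg` columns, classed `deg_table`.
#' @export
call_degs <- function(table, config = de_config()) {
  if (nrow(table) == 0) {
    table$fdr <- numeric(0)
    table$is_deg <- logical(0)
  } else {
    table$fdr <- adjust_bh(table$p_value)
    table$is_deg <- table$fdr <= config$fdr_de_threshold
  }
  attr(table, "fdr_de_threshold") <- config$fdr_de_threshold
  class(table) <- c("deg_table", "data.frame")
  table
}

#' Run the full differential-expression stage
#'
#' Convenience wrapper: size factors, dispersions, Wald test and DEG calls
#' in one step.
#'
#' @inheritParams nb_wald_test
#' @param config A [de_config()].
#' @return A `deg_table` (see [call_degs()]) carrying the size factors and
#'   dispersions as attributes.
#' @export
de_analysis <- function(counts, groups,
                        contrast = c("malignant", "nonmalignant"),
                        config = de_config()) {
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, groups,
                               dispersion_floor = config$dispersion_floor)
  tab <- nb_wald_test(counts, sf, disp, groups, contrast = contrast,
                      lfc_pseudocount = config$lfc_pseudocount)
  tab <- call_degs(tab, config)
  attr(tab, "size_factors") <- sf
  attr(tab, "dispersions") <- disp
  tab
}

#' Principal-component ordination of samples over DEG rows
#'
#' Projects samples onto principal components of
#' `log2(normalized count + offset)` restricted to the differentially
#' expressed genes, the standard visual check that the expression signal
#' separates the two groups.
#'
#' @inheritParams estimate_dispersions
#' @param deg_genes Character vector of gene identifiers (rows) to
#'   ordinate over; typically the DEG set.
#' @param pseudo_log_offset Pseudo-count for the log transform.
#' @return List with `coords` (samples x components score matrix) and
#'   `variance_fraction` (non-increasing, sums to at most 1).
#' @export
ordinate_samples <- function(counts, size_factors, deg_genes,
                             pseudo_log_offset = 1) {
  missing_g <- setdiff(deg_genes, rownames(counts))
  if (length(missing_g) > 0) {
    stopf("%d gene(s) not present in the count matrix", length(missing_g))
  }
  if (length(deg_genes) < 2) stopf("need at least 2 genes to ordinate")
  norm <- sweep(counts[deg_genes, , drop = FALSE], 2, size_factors, "/")
  x <- t(log2(norm + pseudo_log_offset))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  vf <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  list(coords = pc$x, variance_fraction = vf)
}
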