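#' Screening configuration
#'
#' Thresholds of the biomarker screen. `fc_threshold` is the absolute
#' log2 fold-change defining "strongly deregulated" and is inclusive by
#' default (a gene at exactly +/-2 qualifies); set `fc_inclusive = FALSE`
#' for the strict variant. `expression_percentile` is the percentile of
#' group-median normalized counts a gene must strictly exceed in at least
#' one group.
#'
#' @param fc_threshold Positive log2 fold-change magnitude, default 2.
#' @param expression_percentile Percentile in (0, 100), default 40.
#' @param fc_inclusive Whether the fold-change boundary is inclusive.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(fc_threshold = 2, expression_percentile = 40,
                          fc_inclusive = TRUE) {
  check_positive(fc_threshold, "fc_threshold")
  if (expression_percentile <= 0 || expression_percentile >= 100) {
    stopf("'expression_percentile' must lie in (0, 100)")
  }
  structure(list(fc_threshold = fc_threshold,
                 expression_percentile = expression_percentile,
                 fc_inclusive = isTRUE(fc_inclusive)),
            class = "screen_config")
}

median_norm_columns <- function(deg_table) {
  cols <- grep("^median_norm_", names(deg_table), value = TRUE)
  if (length(cols) != 2) {
    stopf("deg_table must carry two 'median_norm_<group>' columns")
  }
  cols
}

#' Expression-percentile filter
#'
#' A gene passes when its group-median normalized count is strictly above
#' the empirical percentile (linear-interpolation estimator) of all tested
#' genes' group medians, in at least one of the two sample groups. The
#' percentile is computed per group over every gene in the table, zeros
#' included.
#'
#' @param deg_table A table carrying `median_norm_<group>` columns, as
#'   produced by [nb_wald_test()].
#' @param percentile Percentile in (0, 100), default 40.
#' @return Logical vector, one element per gene.
#' @export
expression_percentile_filter <- function(deg_table, percentile = 40) {
  cols <- median_norm_columns(deg_table)
  pass <- rep(FALSE, nrow(deg_table))
  for (cl in cols) {
    thr <- quantile(deg_table[[cl]], percentile / 100, type = 7,
                    names = FALSE)
    pass <- pass | (deg_table[[cl]] > thr)
  }
  pass
}

#' Screen for strongly deregulated superpathway genes (the S tier)
#'
#' A gene is in the S tier when it (a) is differentially expressed, (b) has
#' `|log2fc|` at or beyond the fold-change threshold, (c) passes the
#' expression-percentile filter in at least one group, and (d) belongs to
#' the gene union of a superpathway.
#'
#' @param deg_table A `deg_table` (see [call_degs()]).
#' @param superpathway_genes Character vector: union of superpathway member
#'   genes, in the same namespace as `deg_table$gene_id`.
#' @param config A [screen_config()].
#' @return `data.frame` with per-gene columns `gene_id`, `is_deg`,
#'   `log2fc`, `is_strong_fc`, `passes_expression`, `in_superpathway`,
#'   `is_deg_s`.
#' @export
screen_deg_s <- function(deg_table, superpathway_genes,
                         config = screen_config()) {
  fc <- config$fc_threshold
  strong <- if (config$fc_inclusive) {
    deg_table$log2fc >= fc | deg_table$log2fc <= -fc
  } else {
    deg_table$log2fc > fc | deg_table$log2fc < -fc
  }
  pass <- expression_percentile_filter(deg_table,
                                       config$expression_percentile)
  in_sp <- deg_table$gene_id %in% superpathway_genes
  data.frame(gene_id = deg_table$gene_id,
             is_deg = deg_table$is_deg,
             log2fc = deg_table$log2fc,
             is_strong_fc = strong,
             passes_expression = pass,
             in_superpathway = in_sp,
             is_deg_s = deg_table$is_deg & strong & pass & in_sp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen for database-associated genes (the D tier)
#'
#' A gene is in the D tier when it is differentially expressed and carries
#' at least one of the evidence-channel flags (prostate-elevated in HPA,
#' "prostate cancer" pathway member, proto-oncogene / tyrosine kinase,
#' literature, human assay ortholog, druggable). Genes absent from the
#' catalog default to all flags false.
#'
#' @param deg_table A `deg_table`.
#' @param catalog Evidence catalog: `data.frame` with `gene_id` plus one
#'   0/1 or logical column per channel.
#' @return `data.frame` with `gene_id`, `is_deg`, the channel flags, and
#'   `is_deg_d`; channel column names are carried in the `channels`
#'   attribute.
#' @export
screen_deg_d <- function(deg_table, catalog) {
  if (!"gene_id" %in% names(catalog)) stopf("catalog needs a gene_id column")
  channels <- setdiff(names(catalog), "gene_id")
  if (length(channels) == 0) stopf("catalog has no evidence channels")
  if (anyDuplicated(catalog$gene_id)) {
    stopf("catalog contains duplicate gene ids")
  }
  idx <- match(deg_table$gene_id, catalog$gene_id)
  flags <- matrix(FALSE, nrow(deg_table), length(channels),
                  dimnames = list(NULL, channels))
  found <- !is.na(idx)
  for (ch in channels) {
    v <- as.logical(catalog[[ch]][idx[found]])
    v[is.na(v)] <- FALSE
    flags[found, ch] <- v
  }
  out <- data.frame(gene_id = deg_table$gene_id,
                    is_deg = deg_table$is_deg,
                    flags,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$is_deg_d <- deg_table$is_deg & rowSums(flags) > 0
  attr(out, "channels") <- channels
  out
}

#' Intersect the S and D tiers
#'
#' Combines the per-gene results of [screen_deg_s()] and [screen_deg_d()]
#' and flags the intersection tier (`is_deg_sd`), the study's top
#' biomarker candidates.
#'
#' @param s_result Output of [screen_deg_s()].
#' @param d_result Output of [screen_deg_d()] on the same genes.
#' @return A `screen_result` data frame with all component flags and
#'   `is_deg_s`, `is_deg_d`, `is_deg_sd`.
#' @export
intersect_deg_sd <- function(s_result, d_result) {
  if (!identical(s_result$gene_id, d_result$gene_id)) {
    stopf("S and D results must cover the same genes in the same order")
  }
  channels <- attr(d_result, "channels")
  out <- cbind(s_result,
               d_result[c(channels, "is_deg_d")])
  out$is_deg_sd <- out$is_deg_s & out$is_deg_d
  attr(out, "channels") <- channels
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Run the full three-tier screen
#'
#' @inheritParams screen_deg_s
#' @inheritParams screen_deg_d
#' @return A `screen_result` (see [intersect_deg_sd()]).
#' @export
screen_genes <- function(deg_table, superpathway_genes, catalog,
                         config = screen_config()) {
  intersect_deg_sd(screen_deg_s(deg_table, superpathway_genes, config),
                   screen_deg_d(deg_table, catalog))
}

#' Disjoint intersection (UpSet) accounting
#'
#' Assigns every gene in the union of the S and D tiers to exactly one
#' combination of the seven grouping criteria (the six evidence channels
#' plus S-tier membership) and counts each combination. The cells are
#' pairwise disjoint and sum to the size of the union.
#'
#' @param result A `screen_result`.
#' @return `data.frame` with one logical column per criterion plus a
#'   `count` column, sorted by decreasing count.
#' @export
upset_counts <- function(result) {
  channels <- attr(result, "channels")
  in_union <- result$is_deg_s | result$is_deg_d
  crit <- c(channels, "deg_s")
  sub <- result[in_union, , drop = FALSE]
  flags <- data.frame(lapply(channels, function(ch) as.logical(sub[[ch]])))
  names(flags) <- channels
  flags$deg_s <- sub$is_deg_s
  if (nrow(flags) == 0) {
    out <- flags
    out$count <- integer(0)
    return(out)
  }
  key <- do.call(paste, c(flags, sep = "\r"))
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  out <- data.frame(matrix(as.logical(parts), nrow = nrow(parts),
                           dimnames = list(NULL, crit)))
  out$count <- as.integer(tab)
  out[order(-out$count), , drop = FALSE]
}

#' Headline summary statistics of the screen
#'
#' Computes the study's reporting arithmetic from a screen result, with
#' all percentage shares rounded to the nearest integer: the share of
#' upregulated DEGs, the shares of strongly up- and downregulated DEGs,
#' the upregulated share among superpathway DEGs, the D-tier share of all
#' DEGs, and the SD-tier share of the D tier. With zero DEGs all shares
#' are `NA` (never a division by zero).
#'
#' @param result A `screen_result`.
#' @param fc_threshold Fold-change magnitude for the "strong" shares.
#' @return Named list of counts and integer percentages.
#' @export
report_summary <- function(result, fc_threshold = 2) {
  deg <- result[result$is_deg, , drop = FALSE]
  n_deg <- nrow(deg)
  n_up <- sum(deg$log2fc > 0)
  n_strong_up <- sum(deg$log2fc >= fc_threshold)
  n_strong_down <- sum(deg$log2fc <= -fc_threshold)
  sp_deg <- deg[deg$in_superpathway, , drop = FALSE]
  n_sp <- nrow(sp_deg)
  n_sp_up <- sum(sp_deg$log2fc > 0)
  n_d <- sum(result$is_deg_d)
  n_s <- sum(result$is_deg_s)
  n_sd <- sum(result$is_deg_sd)
  channels <- attr(result, "channels")
  d_rows <- result[result$is_deg_d, , drop = FALSE]
  channel_counts <- vapply(channels, function(ch) sum(d_rows[[ch]]),
                           integer(1))
  n_multi <- sum(rowSums(as.matrix(d_rows[channels])) >= 2)
  list(n_genes = nrow(result),
       n_degs = n_deg,
       n_up = n_up,
       pct_up = share_pct(n_up, n_deg),
       n_down = n_deg - n_up,
       n_strong_up = n_strong_up,
       pct_strong_up = share_pct(n_strong_up, n_deg),
       n_strong_down = n_strong_down,
       pct_strong_down = share_pct(n_strong_down, n_deg),
       n_superpathway_degs = n_sp,
       n_superpathway_up = n_sp_up,
       pct_superpathway_up = share_pct(n_sp_up, n_sp),
       n_deg_s = n_s,
       n_deg_d = n_d,
       pct_deg_d = share_pct(n_d, n_deg),
       n_deg_sd = n_sd,
       pct_deg_sd = share_pct(n_sd, n_d),
       n_multi_channel = n_multi,
       pct_multi_channel = share_pct(n_multi, n_d),
       channel_counts = as.list(channel_counts))
}
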