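# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle is written from the definition, not from the
# package's implementation path.

# Benjamini-Hochberg from the definition:
# q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[ord] >= p[i])
    q[i] <- min(1, min(m * p[ord][js] / js))
  }
  q
}

# Hypergeometric upper tail P[X >= k] by exhaustive enumeration of all
# size-n draws from an N-element urn with K marked elements.
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Naive complete-linkage agglomeration on a distance matrix, returning
# cluster labels for a k-cut.
complete_linkage_brute <- function(D, k) {
  clusters <- as.list(seq_len(nrow(D)))
  while (length(clusters) > k) {
    best <- list(d = Inf, i = NA, j = NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best$d) best <- list(d = d, i = i, j = j)
      }
    }
    clusters[[best$j]] <- c(clusters[[best$j]], clusters[[best$i]])
    clusters[[best$i]] <- NULL
  }
  lab <- integer(nrow(D))
  for (c in seq_along(clusters)) lab[clusters[[c]]] <- c
  lab
}

# Are two flat clusterings the same partition (up to label names)?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Random symmetric overlap-coefficient-like matrix with distinct
# off-diagonal entries (ties have probability zero).
random_oc_matrix <- function(n) {
  m <- diag(1, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  dimnames(m) <- list(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
  m
}

# Screen-result fixture with explicit flag columns; channels default to
# the catalog's six evidence channels.
make_screen_result <- function(df,
                               channels = c("hpa_prostate", "pca_pathway",
                                            "oncogene_tk", "literature",
                                            "assay", "druggable")) {
  for (ch in channels) if (is.null(df[[ch]])) df[[ch]] <- FALSE
  for (col in c("is_deg", "is_strong_fc", "passes_expression",
                "in_superpathway", "is_deg_s", "is_deg_d", "is_deg_sd")) {
    if (is.null(df[[col]])) df[[col]] <- FALSE
  }
  if (is.null(df$log2fc)) df$log2fc <- 0
  attr(df, "channels") <- channels
  class(df) <- c("screen_result", "data.frame")
  df
}

# Minimal deg_table fixture from explicit vectors.
make_deg_table <- function(gene_id, log2fc = 0, fdr = 0, is_deg = NULL,
                           med_mal = 10, med_non = 10) {
  n <- length(gene_id)
  df <- data.frame(gene_id = gene_id,
                   base_mean = rep_len(10, n),
                   log2fc = rep_len(log2fc, n),
                   se = rep_len(0.1, n),
                   wald_stat = rep_len(0, n),
                   p_value = rep_len(fdr, n),
                   fdr = rep_len(fdr, n),
                   stringsAsFactors = FALSE)
  df$median_norm_malignant <- rep_len(med_mal, n)
  df$median_norm_nonmalignant <- rep_len(med_non, n)
  df$is_deg <- if (is.null(is_deg)) df$fdr <= 1e-5 else rep_len(is_deg, n)
  class(df) <- c("deg_table", "data.frame")
  df
}

# Small simulation configuration for fast module tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_genes = 600, pathways_per_block = 2, pathway_size = 20,
             seed = seed, ...)
}
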