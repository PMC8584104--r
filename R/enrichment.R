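#' Map genes through an ortholog table
#'
#' Translates gene identifiers into the annotation namespace (e.g. canine
#' Ensembl genes to their human orthologs). One-to-many relations are
#' honoured: every target of an input gene is returned. Genes without any
#' ortholog are dropped; their number is attached as the `n_unmapped`
#' attribute and reported via `message()`.
#'
#' @param genes Character vector of source-namespace gene identifiers.
#' @param map Data frame with columns `source_gene` and `target_gene`
#'   (duplicate pairs not allowed).
#' @param quiet Suppress the dropped-gene message.
#' @return Character vector of unique target identifiers.
#' @export
map_to_background <- function(genes, map, quiet = FALSE) {
  stopifnot(all(c("source_gene", "target_gene") %in% names(map)))
  if (anyDuplicated(map[c("source_gene", "target_gene")])) {
    stopf("ortholog map contains duplicate pairs")
  }
  genes <- unique(genes)
  hit <- map$source_gene %in% genes
  targets <- unique(map$target_gene[hit])
  n_unmapped <- sum(!genes %in% map$source_gene)
  if (n_unmapped > 0 && !quiet) {
    message(n_unmapped, " gene(s) without orthologs dropped")
  }
  structure(targets, n_unmapped = n_unmapped)
}

#' Hypergeometric over-representation test across a pathway collection
#'
#' For each pathway, tests whether differentially expressed genes are
#' over-represented among its members relative to the background: with `N`
#' background genes, `K` pathway members in the background, `n` DEGs and
#' `k` DEG members, the one-sided upper-tail p-value is `P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)`. P-values are BH-adjusted across the
#' collection and a pathway is enriched when `fdr <= fdr_threshold`
#' (inclusive).
#'
#' The optional EASE variant discounts one DEG member (`P[X >= k - 1]`),
#' mimicking the more conservative score used by the DAVID web service;
#' the plain hypergeometric tail is the default.
#'
#' @param deg_set Character vector of DEGs, a subset of `background`.
#' @param collection Named list of pathway member vectors (a parsed GMT).
#' @param background Character vector, the gene universe for the test.
#' @param fdr_threshold Enrichment FDR cutoff (inclusive), default 0.05.
#' @param ease Use the EASE-style discounted tail instead of the plain one.
#' @return `data.frame` with columns `pathway_id`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, `is_enriched`.
#' @export
#' @examples
#' bg <- paste0("g", 1:10)
#' test_enrichment(bg[1:5], list(pw = bg[1:5]), bg)$p_value  # 1/choose(10,5)
test_enrichment <- function(deg_set, collection, background,
                            fdr_threshold = 0.05, ease = FALSE) {
  background <- unique(background)
  if (length(background) == 0) stopf("background is empty")
  deg_set <- unique(deg_set)
  if (!all(deg_set %in% background)) {
    stopf("deg_set must be a subset of the background")
  }
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    stopf("collection must have unique pathway names")
  }
  N <- length(background)
  n <- length(deg_set)
  members <- lapply(collection, function(g) intersect(unique(g), background))
  K <- vapply(members, length, integer(1))
  k <- vapply(members, function(g) length(intersect(g, deg_set)), integer(1))
  k_test <- if (ease) pmax(k - 1L, 0L) else k
  p <- ifelse(k_test == 0, 1, phyper(k_test - 1, K, N - K, n,
                                     lower.tail = FALSE))
  fdr <- adjust_bh(p)
  data.frame(pathway_id = names(collection),
             k = k, K = K, n = n, N = N,
             p_value = unname(p), fdr = unname(fdr),
             is_enriched = unname(fdr <= fdr_threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split pathway DEG members by fold-change direction
#'
#' Adds, for every pathway in an enrichment result, how many of its DEG
#' members are up- and downregulated, and flags the pathway "upregulated"
#' when ups outnumber downs. Directions come from a named log2 fold-change
#' vector in the same gene namespace as the pathway members (for
#' ortholog-mapped pathways, build it with [target_log2fc()]).
#'
#' @param result An enrichment result from [test_enrichment()].
#' @param collection The pathway collection the result was computed on.
#' @param deg_log2fc Named numeric: log2 fold-change for each DEG in the
#'   collection's namespace.
#' @param background Optional background to intersect members with, so the
#'   counts match the enrichment `k` column.
#' @return `result` with `n_up`, `n_down` and `upregulated` columns;
#'   `n_up + n_down == k` for every pathway.
#' @export
direction_split <- function(result, collection, deg_log2fc,
                            background = NULL) {
  deg <- names(deg_log2fc)
  counts <- t(vapply(result$pathway_id, function(id) {
    g <- unique(collection[[id]])
    if (!is.null(background)) g <- intersect(g, background)
    m <- intersect(g, deg)
    up <- sum(deg_log2fc[m] > 0)
    c(up, length(m) - up)
  }, numeric(2)))
  result$n_up <- as.integer(counts[, 1])
  result$n_down <- as.integer(counts[, 2])
  result$upregulated <- result$n_up > result$n_down
  result
}

#' Log2 fold-changes in the ortholog target namespace
#'
#' Carries DEG fold-changes across the ortholog map so pathway-level
#' direction counts can be computed in the annotation namespace. When
#' several source genes map to one target, the fold-change with the
#' largest magnitude is retained.
#'
#' @param deg_table A `deg_table` (see [call_degs()]).
#' @param map Ortholog map data frame (`source_gene`, `target_gene`).
#' @return Named numeric vector over mapped DEG targets.
#' @export
target_log2fc <- function(deg_table, map) {
  deg <- deg_table[deg_table$is_deg, c("gene_id", "log2fc")]
  hit <- map[map$source_gene %in% deg$gene_id, ]
  if (nrow(hit) == 0) return(setNames(numeric(0), character(0)))
  lfc <- deg$log2fc[match(hit$source_gene, deg$gene_id)]
  best <- tapply(lfc, hit$target_gene, function(v) v[which.max(abs(v))])
  setNames(as.numeric(best), names(best))
}
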