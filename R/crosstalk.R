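#' Overlap coefficient between two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`: 1 when one set contains the other,
#' 0 when they are disjoint. Undefined (an error) when both sets are empty.
#'
#' @param set_a,set_b Character vectors (duplicates are ignored).
#' @return A number in `[0, 1]`.
#' @export
overlap_coefficient <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0 && length(b) == 0) {
    stopf("overlap coefficient is undefined for two empty sets")
  }
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise overlap-coefficient matrix for a pathway collection
#'
#' Cross-talk between pathways is quantified by the overlap coefficient of
#' their member sets; the companion distance used for clustering is one
#' minus this matrix. Membership can be restricted to an enrichment
#' background first, so that the cross-talk structure matches what the
#' enrichment stage tested.
#'
#' @param collection Named list of pathway member vectors.
#' @param background Optional gene universe to intersect members with.
#' @return Symmetric numeric matrix with unit diagonal and pathway ids as
#'   dimnames.
#' @export
overlap_matrix <- function(collection, background = NULL) {
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    stopf("collection must have unique pathway names")
  }
  sets <- lapply(collection, function(g) {
    g <- unique(g)
    if (!is.null(background)) g <- intersect(g, background)
    g
  })
  np <- length(sets)
  m <- diag(1, np)
  dimnames(m) <- list(names(sets), names(sets))
  if (np < 2) return(m)
  for (i in seq_len(np - 1)) {
    for (j in seq(i + 1, np)) {
      m[i, j] <- m[j, i] <- overlap_coefficient(sets[[i]], sets[[j]])
    }
  }
  m
}

#' Cluster pathways into superpathways
#'
#' Complete-linkage hierarchical clustering on the distance
#' `1 - overlap coefficient`, with the tree cut into exactly `k` clusters
#' (the default) or, alternatively, at a fixed merge height `h`. Given the
#' same matrix the result is deterministic.
#'
#' @param oc_matrix Symmetric overlap-coefficient matrix from
#'   [overlap_matrix()].
#' @param k Number of superpathways to cut the dendrogram into.
#' @param h Optional height threshold used instead of `k`.
#' @return List of class `superpathway_assignment` with elements `labels`
#'   (named integer cluster labels), `k`, and `tree` (the `hclust` object).
#' @export
cluster_superpathways <- function(oc_matrix, k = 5, h = NULL) {
  if (!isTRUE(all.equal(oc_matrix, t(oc_matrix)))) {
    stopf("overlap matrix must be symmetric")
  }
  np <- nrow(oc_matrix)
  if (is.null(h)) {
    if (k < 1 || k > np) {
      stopf("k must be between 1 and the number of pathways (%d)", np)
    }
  }
  d <- as.dist(1 - oc_matrix)
  tree <- hclust(d, method = "complete")
  labels <- if (is.null(h)) cutree(tree, k = k) else cutree(tree, h = h)
  structure(list(labels = labels, k = length(unique(labels)), tree = tree),
            class = "superpathway_assignment")
}

#' Per-superpathway summaries
#'
#' For each cluster: its member pathways, the union of their genes, the
#' number and fraction of those genes that are differentially expressed,
#' and the cross-talk summary "mean of median overlap" — for each member
#' pathway take the median overlap coefficient to every other member, then
#' average over members. Singleton clusters have no within-cluster overlap
#' and are reported as `NA`.
#'
#' @param assignment A `superpathway_assignment`.
#' @param collection Pathway collection (same namespace as `deg_set`).
#' @param deg_set Character vector of differentially expressed genes.
#' @param oc_matrix The overlap matrix the clustering was computed on.
#' @param background Optional gene universe to intersect members with.
#' @return `data.frame` with one row per superpathway: `superpathway`,
#'   `n_pathways`, `n_genes`, `n_degs`, `fraction_de`,
#'   `mean_of_median_overlap`, plus a `genes` list-column of gene unions.
#' @export
summarize_superpathways <- function(assignment, collection, deg_set,
                                    oc_matrix, background = NULL) {
  labels <- assignment$labels
  ids <- names(labels)
  out <- lapply(sort(unique(labels)), function(cl) {
    member <- ids[labels == cl]
    genes <- unique(unlist(lapply(collection[member], function(g) {
      g <- unique(g)
      if (!is.null(background)) g <- intersect(g, background)
      g
    }), use.names = FALSE))
    n_degs <- length(intersect(genes, deg_set))
    mmo <- if (length(member) < 2) NA_real_ else {
      mean(vapply(member, function(p) {
        median(oc_matrix[p, setdiff(member, p)])
      }, numeric(1)))
    }
    data.frame(superpathway = cl,
               n_pathways = length(member),
               n_genes = length(genes),
               n_degs = n_degs,
               fraction_de = if (length(genes) > 0) n_degs / length(genes) else 0,
               mean_of_median_overlap = mmo,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$genes <- lapply(sort(unique(labels)), function(cl) {
    member <- ids[labels == cl]
    unique(unlist(lapply(collection[member], function(g) {
      g <- unique(g)
      if (!is.null(background)) g <- intersect(g, background)
      g
    }), use.names = FALSE))
  })
  res
}

#' Per-pathway DEG composition
#'
#' The stacked-bar accounting of each pathway: how many members it has,
#' how many are DEGs, and how the DEG members split by direction. A
#' pathway counts as upregulated when its upregulated DEG members
#' outnumber the downregulated ones.
#'
#' @param collection Named list of pathway member vectors.
#' @param deg_log2fc Named numeric log2 fold-changes of the DEGs, in the
#'   collection's namespace.
#' @param background Optional gene universe to intersect members with.
#' @return `data.frame` with `pathway_id`, `n_members`, `n_degs`, `n_up`,
#'   `n_down`, `fraction_de`, `upregulated`.
#' @export
pathway_de_composition <- function(collection, deg_log2fc,
                                   background = NULL) {
  deg <- names(deg_log2fc)
  rows <- lapply(names(collection), function(id) {
    g <- unique(collection[[id]])
    if (!is.null(background)) g <- intersect(g, background)
    m <- intersect(g, deg)
    up <- sum(deg_log2fc[m] > 0)
    data.frame(pathway_id = id, n_members = length(g),
               n_degs = length(m), n_up = up, n_down = length(m) - up,
               fraction_de = if (length(g) > 0) length(m) / length(g) else 0,
               upregulated = up > length(m) - up,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a superpathway dendrogram in Newick format
#'
#' @param assignment A `superpathway_assignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(assignment, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stopf("Newick export requires the 'ape' package")
  }
  phy <- ape::as.phylo(assignment$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
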