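#' Build a confidence-filtered protein-protein interaction network
#'
#' Induces the subgraph of a weighted undirected edge list on a gene
#' universe, keeping only interactions with confidence strictly greater
#' than `min_confidence`. Genes with no retained interaction stay in the
#' network as isolated nodes, so the mean degree reflects the full
#' universe.
#'
#' @param edges `data.frame` with columns `gene_a`, `gene_b`,
#'   `confidence`; undirected, no self-loops, no duplicate unordered
#'   pairs, confidences in `[0, 1]`.
#' @param genes Character vector, the node universe (non-empty).
#' @param min_confidence Strict lower confidence bound, default 0.4.
#' @return List of class `ppi_network`: `graph` (igraph), `degree` (named
#'   integer), `mean_degree`, `hubs` (see [detect_hubs()]), and the
#'   retained `edges`.
#' @export
build_network <- function(edges, genes, min_confidence = 0.4) {
  if (length(genes) == 0) stopf("gene universe is empty")
  if (anyDuplicated(genes)) stopf("gene universe contains duplicates")
  stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  bad_conf <- which(edges$confidence < 0 | edges$confidence > 1 |
                      is.na(edges$confidence))
  self <- which(edges$gene_a == edges$gene_b)
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  dup <- which(duplicated(key))
  if (length(bad_conf) || length(self) || length(dup)) {
    msg <- c(
      if (length(bad_conf)) sprintf("confidence outside [0,1] at row(s) %s",
                                    paste(utils::head(bad_conf, 5), collapse = ", ")),
      if (length(self)) sprintf("self-loop(s) at row(s) %s",
                                paste(utils::head(self, 5), collapse = ", ")),
      if (length(dup)) sprintf("duplicate pair(s) at row(s) %s",
                               paste(utils::head(dup, 5), collapse = ", ")))
    stopf("malformed edge list: %s", paste(msg, collapse = "; "))
  }
  keep <- edges$confidence > min_confidence &
    edges$gene_a %in% genes & edges$gene_b %in% genes
  kept <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE))
  deg <- igraph::degree(g)
  mean_deg <- if (length(genes) > 0) 2 * nrow(kept) / length(genes) else 0
  net <- structure(list(graph = g, degree = deg, mean_degree = mean_deg,
                        edges = kept, min_confidence = min_confidence),
                   class = "ppi_network")
  net$hubs <- detect_hubs(net)
  net
}

#' Detect hub genes
#'
#' A hub is a node whose degree strictly exceeds the network's (unrounded)
#' mean degree. In a k-regular or empty graph nothing exceeds the mean, so
#' there are no hubs. For replication against published hub lists that
#' used a rounded integer mean, a fixed threshold can be supplied instead.
#'
#' @param net A `ppi_network`.
#' @param threshold Optional fixed degree threshold replacing the mean.
#' @return Character vector of hub gene identifiers.
#' @export
detect_hubs <- function(net, threshold = NULL) {
  thr <- if (is.null(threshold)) net$mean_degree else threshold
  names(net$degree)[net$degree > thr]
}

#' Network summary statistics
#'
#' @param net A `ppi_network`.
#' @return List: `n_nodes`, `n_edges`, `mean_degree` (unrounded),
#'   `mean_degree_rounded`, `max_degree_gene` (lexicographically first on
#'   ties), `max_degree`, `max_degree_tie` (whether a tie occurred) and
#'   `n_hubs`.
#' @export
network_stats <- function(net) {
  deg <- net$degree
  if (length(deg) == 0) {
    return(list(n_nodes = 0L, n_edges = 0L, mean_degree = 0,
                mean_degree_rounded = 0L, max_degree_gene = NA_character_,
                max_degree = 0L, max_degree_tie = FALSE, n_hubs = 0L))
  }
  mx <- max(deg)
  top <- sort(names(deg)[deg == mx])
  list(n_nodes = length(deg),
       n_edges = nrow(net$edges),
       mean_degree = net$mean_degree,
       mean_degree_rounded = as.integer(round(net$mean_degree)),
       max_degree_gene = top[1],
       max_degree = as.integer(mx),
       max_degree_tie = length(top) > 1,
       n_hubs = length(net$hubs))
}

#' Neighborhood of a set of hubs
#'
#' Union of the direct interaction partners of the queried hubs,
#' intersected with a gene universe. A queried hub appears in the result
#' only if it is itself a neighbor of another queried hub.
#'
#' @param net A `ppi_network`.
#' @param hub_subset Character vector of genes to query (must be nodes).
#' @param universe Character vector to intersect the neighborhood with.
#' @return List with `genes` (sorted character vector) and `count`.
#' @export
hub_neighborhood <- function(net, hub_subset, universe) {
  missing_h <- setdiff(hub_subset, names(net$degree))
  if (length(missing_h) > 0) {
    stopf("gene(s) not in network: %s",
          paste(utils::head(missing_h, 5), collapse = ", "))
  }
  if (length(hub_subset) == 0) return(list(genes = character(0), count = 0L))
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(net$graph, hub_subset),
    function(v) igraph::as_ids(v)), use.names = FALSE))
  genes <- sort(intersect(nb, universe))
  list(genes = genes, count = length(genes))
}

#' @export
print.ppi_network <- function(x, ...) {
  st <- network_stats(x)
  cat(sprintf(
    "PPI network: %d nodes, %d edges (confidence > %g), mean degree %.2f, %d hubs\n",
    st$n_nodes, st$n_edges, x$min_confidence, st$mean_degree, st$n_hubs))
  invisible(x)
}
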