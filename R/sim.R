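#' Simulation configuration
#'
#' Parameters of the synthetic study generator. The defaults emulate the
#' design being modelled: 10 malignant versus 14 nonmalignant samples,
#' around fifty pathways organized in five cross-talking blocks, roughly
#' 40% differentially expressed members per pathway, and a sparse PPI
#' graph with a handful of planted hubs. Baseline expression is log-normal
#' across genes and counts are negative-binomial with
#' `variance = mu + dispersion * mu^2`.
#'
#' @param n_genes Number of simulated genes.
#' @param group_sizes Integer pair: malignant and nonmalignant sample
#'   counts (each at least 2).
#' @param de_fraction Overall fraction of genes with a planted effect.
#' @param effect_log2fc Magnitude of planted log2 fold-changes; the sign
#'   is random per gene.
#' @param baseline_mean_log_mu,baseline_mean_log_sigma Mean and standard
#'   deviation of log baseline expression across genes.
#' @param dispersion Common NB dispersion `alpha`; 0 selects the Poisson
#'   limit.
#' @param libsize_log_sigma Standard deviation of per-sample log library
#'   size factors (geometric mean forced to 1), making normalization
#'   non-trivial.
#' @param n_superpathway_blocks,pathways_per_block,pathway_size Shape of
#'   the planted pathway collection.
#' @param within_block_overlap,between_block_overlap Target overlap
#'   coefficients inside and across blocks; within must exceed between for
#'   the structure to be recoverable, and their sum cannot exceed 1.
#' @param de_member_fraction Fraction of each pathway's members drawn from
#'   the planted DE genes (when the generator is given them), so pathway
#'   blocks come out enriched.
#' @param evidence_channel_probs Named vector of six per-channel flag
#'   probabilities.
#' @param evidence_correlation Gaussian-copula correlation shared across a
#'   gene's six channels; 0 gives independent channels.
#' @param ppi_within_density,ppi_between_density Edge probabilities for
#'   gene pairs that do / do not share a pathway.
#' @param n_hubs Number of planted hub genes.
#' @param hub_degree_factor Planted hubs are wired to this multiple of the
#'   expected mean degree (at least 3 for reliable recovery).
#' @param ortholog_mapped_fraction Fraction of genes with an ortholog.
#' @param ortholog_one2many_fraction Fraction of mapped genes with two
#'   ortholog targets.
#' @param seed Master seed; each generator draws from its own derived
#'   stream (fixed offsets 0, 101, 211, 307, 401 for counts, pathways,
#'   evidence, PPI and orthologs).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       group_sizes = c(malignant = 10, nonmalignant = 14),
                       de_fraction = 0.1,
                       effect_log2fc = 3,
                       baseline_mean_log_mu = 4,
                       baseline_mean_log_sigma = 1.5,
                       dispersion = 0.1,
                       libsize_log_sigma = 0.3,
                       n_superpathway_blocks = 5,
                       pathways_per_block = 10,
                       pathway_size = 40,
                       within_block_overlap = 0.8,
                       between_block_overlap = 0.05,
                       de_member_fraction = 0.4,
                       evidence_channel_probs = c(hpa_prostate = 0.008,
                                                  pca_pathway = 0.008,
                                                  oncogene_tk = 0.03,
                                                  literature = 0.08,
                                                  assay = 0.01,
                                                  druggable = 0.05),
                       evidence_correlation = 0,
                       ppi_within_density = 0.25,
                       ppi_between_density = 0.002,
                       n_hubs = 5,
                       hub_degree_factor = 3,
                       ortholog_mapped_fraction = 0.95,
                       ortholog_one2many_fraction = 0.02,
                       seed = 1) {
  int_fields <- list(n_genes = n_genes,
                     n_superpathway_blocks = n_superpathway_blocks,
                     pathways_per_block = pathways_per_block,
                     pathway_size = pathway_size, seed = seed)
  for (nm in names(int_fields)) {
    v <- int_fields[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v != round(v)) {
      stopf("'%s' must be a single integer", nm)
    }
  }
  if (length(group_sizes) != 2 || any(group_sizes != round(group_sizes)) ||
      any(group_sizes < 2)) {
    stopf("'group_sizes' must be two integers, each at least 2")
  }
  check_proportion(de_fraction, "de_fraction")
  check_positive(effect_log2fc, "effect_log2fc")
  check_positive(baseline_mean_log_sigma, "baseline_mean_log_sigma",
                 strict = FALSE)
  check_positive(dispersion, "dispersion", strict = FALSE)
  check_positive(libsize_log_sigma, "libsize_log_sigma", strict = FALSE)
  check_proportion(within_block_overlap, "within_block_overlap")
  check_proportion(between_block_overlap, "between_block_overlap")
  if (within_block_overlap + between_block_overlap > 1) {
    stopf("within and between block overlaps cannot sum above 1")
  }
  check_proportion(de_member_fraction, "de_member_fraction")
  if (length(evidence_channel_probs) != 6 ||
      is.null(names(evidence_channel_probs))) {
    stopf("'evidence_channel_probs' must be six named probabilities")
  }
  check_proportion(evidence_channel_probs, "evidence_channel_probs")
  check_proportion(evidence_correlation, "evidence_correlation")
  check_proportion(ppi_within_density, "ppi_within_density")
  check_proportion(ppi_between_density, "ppi_between_density")
  if (n_hubs < 0 || n_hubs != round(n_hubs)) {
    stopf("'n_hubs' must be a non-negative integer")
  }
  check_positive(hub_degree_factor, "hub_degree_factor")
  check_proportion(ortholog_mapped_fraction, "ortholog_mapped_fraction")
  check_proportion(ortholog_one2many_fraction, "ortholog_one2many_fraction")
  cfg <- list(n_genes = as.integer(n_genes),
              group_sizes = setNames(as.integer(group_sizes),
                                     c("malignant", "nonmalignant")),
              de_fraction = de_fraction,
              effect_log2fc = effect_log2fc,
              baseline_mean_log_mu = baseline_mean_log_mu,
              baseline_mean_log_sigma = baseline_mean_log_sigma,
              dispersion = dispersion,
              libsize_log_sigma = libsize_log_sigma,
              n_superpathway_blocks = as.integer(n_superpathway_blocks),
              pathways_per_block = as.integer(pathways_per_block),
              pathway_size = as.integer(pathway_size),
              within_block_overlap = within_block_overlap,
              between_block_overlap = between_block_overlap,
              de_member_fraction = de_member_fraction,
              evidence_channel_probs = evidence_channel_probs,
              evidence_correlation = evidence_correlation,
              ppi_within_density = ppi_within_density,
              ppi_between_density = ppi_between_density,
              n_hubs = as.integer(n_hubs),
              hub_degree_factor = hub_degree_factor,
              ortholog_mapped_fraction = ortholog_mapped_fraction,
              ortholog_one2many_fraction = ortholog_one2many_fraction,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a two-group count matrix with planted differential expression
#'
#' Gene baseline means are log-normal across genes; a `de_fraction` subset
#' of genes has its nonmalignant-group mean multiplied by
#' `2^(+/- effect_log2fc)` with a random sign, so the planted malignant
#' versus nonmalignant log2 fold-change is minus the applied signed
#' effect. Per-sample library-size factors are log-normal with geometric
#' mean 1. Counts are NB with common dispersion (Poisson when the
#' dispersion is 0). Fully seeded: the same configuration reproduces the
#' same matrix bit for bit.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (integer matrix, genes x samples), `samples`
#'   (sample sheet: `sample_id`, `group`, `specimen_type`), and `truth`
#'   (list with `de_genes`, a named vector of planted malignant-over-
#'   nonmalignant log2 effects, and `baseline_mu`, `size_factors`).
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 0))
  ng <- config$n_genes
  n1 <- config$group_sizes[["malignant"]]
  n2 <- config$group_sizes[["nonmalignant"]]
  genes <- sprintf("G%05d", seq_len(ng))

  mu <- rlnorm(ng, config$baseline_mean_log_mu, config$baseline_mean_log_sigma)
  n_de <- round(config$de_fraction * ng)
  de_idx <- if (n_de > 0) sort(sample.int(ng, n_de)) else integer(0)
  sign <- sample(c(-1, 1), n_de, replace = TRUE)

  mu_mal <- mu
  mu_non <- mu
  # effect applied to the second (nonmalignant) group mean
  mu_non[de_idx] <- mu[de_idx] * 2^(sign * config$effect_log2fc)

  ns <- n1 + n2
  sf <- exp(rnorm(ns, 0, config$libsize_log_sigma))
  sf <- sf / exp(mean(log(sf)))

  counts <- matrix(0L, ng, ns)
  for (s in seq_len(ns)) {
    m <- if (s <= n1) mu_mal else mu_non
    counts[, s] <- nb_draw(ng, sf[s] * m, config$dispersion)
  }
  storage.mode(counts) <- "integer"
  sample_ids <- c(sprintf("MAL_%02d", seq_len(n1)),
                  sprintf("NON_%02d", seq_len(n2)))
  dimnames(counts) <- list(genes, sample_ids)
  # specimen mix mirrors the emulated design: 9 tissues per group, the
  # remainder fine-needle aspirates
  specimen <- function(n) c(rep("tissue", min(n, 9)),
                            rep("FNA", max(0, n - 9)))
  samples <- data.frame(sample_id = sample_ids,
                        group = c(rep("malignant", n1),
                                  rep("nonmalignant", n2)),
                        specimen_type = c(specimen(n1), specimen(n2)),
                        stringsAsFactors = FALSE)
  planted <- setNames(log2(mu_mal[de_idx] / mu_non[de_idx]), genes[de_idx])
  list(counts = counts, samples = samples,
       truth = list(de_genes = planted,
                    baseline_mu = setNames(mu, genes),
                    size_factors = setNames(sf, sample_ids)))
}

# Draw n genes from the de / non-de pools at the requested DE fraction,
# removing what is drawn so pathway components stay disjoint.
draw_pool <- function(pools, n, frac_de) {
  n_de <- min(rbinom(1, n, frac_de), length(pools$de))
  n_bg <- n - n_de
  if (n_bg > length(pools$bg)) stopf("gene universe too small for pathways")
  de_pick <- if (n_de > 0) sample(pools$de, n_de) else character(0)
  bg_pick <- if (n_bg > 0) sample(pools$bg, n_bg) else character(0)
  pools$de <- setdiff(pools$de, de_pick)
  pools$bg <- setdiff(pools$bg, bg_pick)
  list(genes = c(de_pick, bg_pick), pools = pools)
}

#' Simulate a pathway collection with planted superpathway blocks
#'
#' Builds `n_superpathway_blocks * pathways_per_block` gene sets of equal
#' size. Pathways in the same block share a common core comprising a
#' `within_block_overlap` fraction of their members; all pathways
#' additionally share a small global set comprising a
#' `between_block_overlap` fraction, so cross-block overlap coefficients
#' equal the between level while within-block coefficients are at least
#' the within level. The remaining members are unique per pathway. When a
#' planted DE gene set is supplied, members are drawn so that roughly
#' `de_member_fraction` of each pathway is differentially expressed,
#' making every block recoverable by enrichment.
#'
#' @param config A [sim_config()].
#' @param universe Character vector of available gene identifiers.
#' @param de_genes Optional character vector of planted DE genes within
#'   `universe`.
#' @return List with `collection` (named list of member vectors) and
#'   `block_of_pathway` (named integer block labels).
#' @export
simulate_pathways <- function(config = sim_config(), universe,
                              de_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(universe) == 0) stopf("universe is empty")
  set.seed(stage_seed(config$seed, 101))
  m <- config$pathway_size
  nb <- config$n_superpathway_blocks
  ppb <- config$pathways_per_block
  core_n <- round(config$within_block_overlap * m)
  shared_n <- round(config$between_block_overlap * m)
  uniq_n <- m - core_n - shared_n
  if (uniq_n < 0) stopf("overlap fractions leave no room for unique members")
  needed <- shared_n + nb * core_n + nb * ppb * uniq_n
  if (needed > length(universe)) {
    stopf("universe of %d genes is smaller than the %d required",
          length(universe), needed)
  }
  de_genes <- intersect(de_genes, universe)
  frac <- if (length(de_genes) > 0) config$de_member_fraction else 0
  pools <- list(de = de_genes, bg = setdiff(universe, de_genes))

  d <- draw_pool(pools, shared_n, frac)
  shared <- d$genes; pools <- d$pools
  collection <- list()
  block_of <- integer(0)
  for (b in seq_len(nb)) {
    d <- draw_pool(pools, core_n, frac)
    core <- d$genes; pools <- d$pools
    for (j in seq_len(ppb)) {
      d <- draw_pool(pools, uniq_n, frac)
      pools <- d$pools
      id <- sprintf("PW%02d_%02d", b, j)
      collection[[id]] <- sort(c(core, shared, d$genes))
      block_of[id] <- b
    }
  }
  list(collection = collection, block_of_pathway = block_of)
}

#' Simulate a per-gene evidence catalog
#'
#' Draws the six boolean evidence channels per gene at the configured
#' marginal probabilities. With `evidence_correlation > 0`, a per-gene
#' latent "well-studied" factor is shared across channels through a
#' Gaussian copula, correlating the flags while preserving the marginals.
#'
#' @param config A [sim_config()].
#' @param universe Character vector of gene identifiers.
#' @return `data.frame`: `gene_id` plus one 0/1 column per channel.
#' @export
simulate_evidence <- function(config = sim_config(), universe) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 211))
  probs <- config$evidence_channel_probs
  rho <- config$evidence_correlation
  n <- length(universe)
  z0 <- rnorm(n)
  out <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (ch in names(probs)) {
    z <- sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(n)
    out[[ch]] <- as.integer(pnorm(z) < probs[[ch]])
  }
  out
}

pair_from_index <- function(idx, n) {
  # unordered pair (i, j), i < j, from a linear index over the n*(n-1)/2
  # pairs enumerated (1,2), (1,3), ..., (1,n), (2,3), ...
  cum <- c(0, cumsum(seq(n - 1, 1)))
  i <- findInterval(idx - 1, cum)
  j <- i + (idx - cum[i])
  cbind(i, j)
}

#' Simulate a PPI edge list with planted hubs
#'
#' Gene pairs sharing at least one pathway are connected with probability
#' `ppi_within_density`, all other pairs with `ppi_between_density`.
#' Planted hub genes are then wired to at least `hub_degree_factor` times
#' the expected mean degree. Structural edges get confidences above the
#' conventional 0.4 reliability cutoff; a layer of low-confidence decoy
#' edges (below 0.4) is added so that confidence filtering is exercised.
#' No self-loops, no duplicate unordered pairs.
#'
#' @param config A [sim_config()].
#' @param universe Character vector of gene identifiers.
#' @param collection Pathway collection over (a subset of) `universe`.
#' @return List with `edges` (`gene_a`, `gene_b`, `confidence`) and
#'   `hub_genes` (character).
#' @export
simulate_ppi <- function(config = sim_config(), universe, collection) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 307))
  n <- length(universe)
  if (n < 2) stopf("need at least two genes for a PPI graph")
  idx_of <- setNames(seq_len(n), universe)

  # unique within-pathway pairs, as keys i*(n+1)+j with i < j
  within_keys <- unique(unlist(lapply(collection, function(g) {
    gi <- sort(idx_of[intersect(g, universe)])
    if (length(gi) < 2) return(numeric(0))
    cmb <- utils::combn(gi, 2)
    cmb[1, ] * (n + 1) + cmb[2, ]
  }), use.names = FALSE))
  n_within <- length(within_keys)
  total_pairs <- n * (n - 1) / 2
  p_w <- config$ppi_within_density
  p_b <- config$ppi_between_density

  keep_within <- if (n_within > 0) {
    within_keys[runif(n_within) < p_w]
  } else numeric(0)

  n_between_draw <- rbinom(1, total_pairs, p_b)
  between_keys <- if (n_between_draw > 0) {
    pr <- pair_from_index(sample(total_pairs, n_between_draw), n)
    k <- pr[, 1] * (n + 1) + pr[, 2]
    setdiff(k, within_keys)
  } else numeric(0)

  edge_keys <- c(keep_within, between_keys)

  # wire planted hubs up to the target degree
  exp_mean_deg <- 2 * (p_w * n_within + p_b * (total_pairs - n_within)) / n
  target <- ceiling(config$hub_degree_factor * exp_mean_deg)
  hub_idx <- if (config$n_hubs > 0) sample.int(n, config$n_hubs) else integer(0)
  for (h in hub_idx) {
    partners <- setdiff(seq_len(n), h)
    keys_h <- ifelse(pmin(h, partners) == h,
                     h * (n + 1) + partners,
                     partners * (n + 1) + h)
    have <- sum(keys_h %in% edge_keys)
    need <- target - have
    if (need > 0) {
      new <- sample(keys_h[!keys_h %in% edge_keys], need)
      edge_keys <- c(edge_keys, new)
    }
  }
  edge_keys <- unique(edge_keys)

  i <- floor(edge_keys / (n + 1))
  j <- edge_keys - i * (n + 1)
  ne <- length(edge_keys)
  conf <- runif(ne, 0.45, 1)

  # decoy edges below the reliability cutoff
  n_decoy <- rbinom(1, total_pairs, p_b)
  decoy_keys <- if (n_decoy > 0) {
    pr <- pair_from_index(sample(total_pairs, n_decoy), n)
    setdiff(pr[, 1] * (n + 1) + pr[, 2], edge_keys)
  } else numeric(0)
  di <- floor(decoy_keys / (n + 1))
  dj <- decoy_keys - di * (n + 1)

  edges <- data.frame(
    gene_a = universe[c(i, di)],
    gene_b = universe[c(j, dj)],
    confidence = round(c(conf, runif(length(decoy_keys), 0.05, 0.35)), 3),
    stringsAsFactors = FALSE)
  list(edges = edges, hub_genes = sort(universe[hub_idx]))
}

#' Simulate a one-to-many ortholog map
#'
#' Maps a configurable fraction of genes to a target-namespace identifier
#' (`H_<gene>`); a small fraction of mapped genes get a second target,
#' exercising one-to-many relations.
#'
#' @param config A [sim_config()].
#' @param universe Character vector of source gene identifiers.
#' @return `data.frame` with `source_gene`, `target_gene`.
#' @export
simulate_ortholog_map <- function(config = sim_config(), universe) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 401))
  n <- length(universe)
  mapped <- universe[runif(n) < config$ortholog_mapped_fraction]
  two <- mapped[runif(length(mapped)) < config$ortholog_one2many_fraction]
  data.frame(
    source_gene = c(mapped, two),
    target_gene = c(paste0("H_", mapped), paste0("H_", two, "b")),
    stringsAsFactors = FALSE)
}

#' Simulate a complete ground-truthed study
#'
#' Chains the individual generators into one coherent input bundle: a
#' count matrix with planted DE genes, an ortholog map, a pathway
#' collection in the ortholog target namespace whose blocks are enriched
#' in (mapped) DE genes, an evidence catalog, and a PPI edge list over the
#' source genes whose density follows pathway co-membership.
#'
#' @param config A [sim_config()].
#' @return List of class `superpath_study`: `config`, `counts`, `samples`,
#'   `ortholog_map`, `collection`, `evidence`, `ppi_edges`, and `truth`
#'   (`de_genes`, `block_of_pathway`, `hub_genes`).
#' @export
simulate_study <- function(config = sim_config()) {
  cm <- simulate_counts(config)
  genes <- rownames(cm$counts)
  map <- simulate_ortholog_map(config, genes)
  target_universe <- sort(unique(map$target_gene))
  de_targets <- map_to_background(names(cm$truth$de_genes), map, quiet = TRUE)
  pw <- simulate_pathways(config, target_universe, de_genes = de_targets)
  evidence <- simulate_evidence(config, genes)
  # source-namespace pathway membership drives PPI density
  collection_source <- lapply(pw$collection, function(members) {
    unique(map$source_gene[map$target_gene %in% members])
  })
  ppi <- simulate_ppi(config, genes, collection_source)
  structure(list(config = config,
                 counts = cm$counts,
                 samples = cm$samples,
                 ortholog_map = map,
                 collection = pw$collection,
                 evidence = evidence,
                 ppi_edges = ppi$edges,
                 truth = list(de_genes = cm$truth$de_genes,
                              block_of_pathway = pw$block_of_pathway,
                              hub_genes = ppi$hub_genes,
                              size_factors = cm$truth$size_factors)),
            class = "superpath_study")
}

#' Write a simulated study to pipeline input files
#'
#' Persists every input of [run_pipeline()] in its on-disk format: counts
#' and sample sheet as TSV, pathways as GMT, ortholog map, evidence
#' catalog and PPI edge list as TSV.
#'
#' @param study A `superpath_study` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "superpath_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                samples = file.path(dir, "samples.tsv"),
                gmt = file.path(dir, "pathways.gmt"),
                orthologs = file.path(dir, "orthologs.tsv"),
                evidence = file.path(dir, "evidence.tsv"),
                ppi = file.path(dir, "ppi.tsv"))
  write_counts(study$counts, study$samples, paths$counts, paths$samples)
  write_gmt(study$collection, paths$gmt)
  write_tsv(study$ortholog_map, paths$orthologs)
  write_tsv(study$evidence, paths$evidence)
  write_tsv(study$ppi_edges, paths$ppi)
  invisible(paths)
}
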