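#' Pipeline configuration
#'
#' Bundles input paths and stage thresholds. The defaults are the study's
#' decision rules: DEG FDR `1e-5`, enrichment FDR `0.05`, five
#' superpathways, inclusive |log2FC| >= 2, 40th expression percentile,
#' and a strict 0.4 PPI confidence cutoff.
#'
#' @param counts,samples,gmt,orthologs,evidence,ppi Input file paths (see
#'   the reader functions in this package for the formats).
#' @param out_dir Optional directory for persisted stage outputs.
#' @param fdr_de DEG FDR threshold (inclusive).
#' @param fdr_enrich Enrichment FDR threshold (inclusive).
#' @param k Number of superpathways to cut the cross-talk dendrogram into.
#' @param fc_threshold,expression_percentile,fc_inclusive Screening
#'   thresholds, see [screen_config()].
#' @param min_confidence Strict PPI confidence cutoff.
#' @param contrast Group contrast, numerator first.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, samples, gmt, orthologs, evidence, ppi,
                            out_dir = NULL,
                            fdr_de = 1e-5, fdr_enrich = 0.05, k = 5,
                            fc_threshold = 2, expression_percentile = 40,
                            fc_inclusive = TRUE, min_confidence = 0.4,
                            contrast = c("malignant", "nonmalignant")) {
  paths <- list(counts = counts, samples = samples, gmt = gmt,
                orthologs = orthologs, evidence = evidence, ppi = ppi)
  missing_f <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing_f) > 0) {
    stopf("input file(s) not found: %s",
          paste(unlist(missing_f), collapse = ", "))
  }
  if (fdr_enrich <= 0 || fdr_enrich >= 1) stopf("'fdr_enrich' must be in (0,1)")
  check_proportion(min_confidence, "min_confidence")
  structure(list(paths = paths, out_dir = out_dir,
                 de = de_config(fdr_de_threshold = fdr_de),
                 fdr_enrich = fdr_enrich, k = k,
                 screen = screen_config(fc_threshold, expression_percentile,
                                        fc_inclusive),
                 min_confidence = min_confidence,
                 contrast = contrast),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; relative
#' input paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  for (key in c("counts", "samples", "gmt", "orthologs", "evidence", "ppi")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  do.call(pipeline_config, cfg)
}

#' Validate pipeline input files
#'
#' Schema-checks every input (duplicate gene rows, malformed GMT lines,
#' missing columns) and reports cross-file identifier consistency, e.g.
#' how many evidence-catalog or PPI genes are absent from the count
#' matrix. Fatal schema problems raise errors naming the offender; soft
#' inconsistencies are returned as diagnostics.
#'
#' @param config A `pipeline_config` (or a named list of paths with the
#'   same elements).
#' @return List of per-file diagnostics (row/column/set counts and
#'   warnings), invisibly printable.
#' @export
validate_inputs <- function(config) {
  paths <- if (inherits(config, "pipeline_config")) config$paths else config
  cm <- read_counts(paths$counts, paths$samples)
  collection <- read_gmt(paths$gmt)
  map <- read_ortholog_map(paths$orthologs)
  ev <- read_evidence_catalog(paths$evidence)
  ppi <- read_ppi_edges(paths$ppi)
  genes <- rownames(cm$counts)
  diag <- list(
    counts = list(n_genes = nrow(cm$counts), n_samples = ncol(cm$counts),
                  groups = table(cm$samples$group)),
    pathways = list(n_pathways = length(collection),
                    sizes = range(lengths(collection))),
    orthologs = list(n_pairs = nrow(map),
                     n_sources = length(unique(map$source_gene)),
                     n_targets = length(unique(map$target_gene)),
                     n_unmapped_counts_genes =
                       sum(!genes %in% map$source_gene)),
    evidence = list(n_genes = nrow(ev),
                    n_channels = ncol(ev) - 1,
                    n_missing_from_counts = sum(!ev$gene_id %in% genes)),
    ppi = list(n_edges = nrow(ppi),
               n_missing_from_counts =
                 sum(!unique(c(ppi$gene_a, ppi$gene_b)) %in% genes)))
  if (diag$evidence$n_missing_from_counts > 0) {
    warning(sprintf("%d evidence-catalog gene(s) absent from the counts",
                    diag$evidence$n_missing_from_counts), call. = FALSE)
  }
  invisible(diag)
}

#' Run the full biomarker-prioritization pipeline
#'
#' Executes the five analysis stages in order — differential expression,
#' ortholog-mapped pathway enrichment, cross-talk clustering into
#' superpathways, three-tier screening, PPI hub analysis — and collects a
#' run report. With fewer DEGs or enriched pathways than a stage needs,
#' downstream tiers come back empty rather than failing. When
#' `config$out_dir` is set, every stage output is persisted as TSV/JSON.
#' The run is deterministic: identical inputs give identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `superpath_report`: `summary` (headline
#'   counts), `deg_table`, `ordination`, `enrichment`, `oc_matrix`,
#'   `assignment`, `superpathways`, `screen`, `upset`, `network`,
#'   `network_stats`, and the thresholds used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  inp <- stage("read_inputs", {
    list(cm = read_counts(config$paths$counts, config$paths$samples),
         collection = read_gmt(config$paths$gmt),
         map = read_ortholog_map(config$paths$orthologs),
         evidence = read_evidence_catalog(config$paths$evidence),
         ppi = read_ppi_edges(config$paths$ppi))
  })
  counts <- inp$cm$counts
  groups <- inp$cm$samples$group

  deg_table <- stage("de", de_analysis(counts, groups,
                                       contrast = config$contrast,
                                       config = config$de))
  deg_genes <- deg_table$gene_id[deg_table$is_deg]

  ordination <- if (length(deg_genes) >= 2) {
    stage("ordination",
          ordinate_samples(counts, attr(deg_table, "size_factors"),
                           deg_genes,
                           config$de$pseudo_log_offset))
  } else NULL

  enr <- stage("enrichment", {
    background <- map_to_background(rownames(counts), inp$map, quiet = TRUE)
    deg_bg <- map_to_background(deg_genes, inp$map, quiet = TRUE)
    lfc_t <- target_log2fc(deg_table, inp$map)
    res <- test_enrichment(deg_bg, inp$collection, background,
                           fdr_threshold = config$fdr_enrich)
    res <- direction_split(res, inp$collection, lfc_t, background)
    list(result = res, background = background, deg_bg = deg_bg,
         lfc_target = lfc_t)
  })
  enriched_ids <- enr$result$pathway_id[enr$result$is_enriched]

  ct <- stage("crosstalk", {
    if (length(enriched_ids) >= max(2, config$k)) {
      sub <- inp$collection[enriched_ids]
      oc <- overlap_matrix(sub, background = enr$background)
      asg <- cluster_superpathways(oc, k = config$k)
      summ <- summarize_superpathways(asg, sub, enr$deg_bg, oc,
                                      background = enr$background)
      comp <- pathway_de_composition(sub, enr$lfc_target,
                                     background = enr$background)
      sp_genes_target <- unique(unlist(summ$genes, use.names = FALSE))
      list(oc = oc, assignment = asg, summary = summ, composition = comp,
           sp_genes_target = sp_genes_target)
    } else {
      list(oc = NULL, assignment = NULL, summary = NULL, composition = NULL,
           sp_genes_target = character(0))
    }
  })
  # superpathway membership back in the source-gene namespace
  sp_genes_source <- unique(
    inp$map$source_gene[inp$map$target_gene %in% ct$sp_genes_target])

  screen <- stage("screening",
                  screen_genes(deg_table, sp_genes_source, inp$evidence,
                               config$screen))
  upset <- stage("screening", upset_counts(screen))

  net_genes <- sort(unique(
    screen$gene_id[screen$is_deg_d | screen$is_deg_s]))
  net <- stage("network", {
    if (length(net_genes) > 0) {
      build_network(inp$ppi, net_genes,
                    min_confidence = config$min_confidence)
    } else NULL
  })
  net_stats <- if (is.null(net)) {
    list(n_nodes = 0L, n_edges = 0L, mean_degree = 0,
         mean_degree_rounded = 0L, max_degree_gene = NA_character_,
         max_degree = 0L, max_degree_tie = FALSE, n_hubs = 0L)
  } else network_stats(net)

  summary <- c(report_summary(screen, config$screen$fc_threshold),
               list(n_enriched_pathways = length(enriched_ids),
                    n_superpathways = if (is.null(ct$assignment)) 0L
                                      else ct$assignment$k,
                    superpathway_sizes = if (is.null(ct$summary)) integer(0)
                                         else ct$summary$n_genes,
                    superpathway_fraction_de =
                      if (is.null(ct$summary)) numeric(0)
                      else ct$summary$fraction_de,
                    pc1_variance_fraction =
                      if (is.null(ordination)) NA_real_
                      else ordination$variance_fraction[1]),
               net_stats[c("n_nodes", "n_edges", "mean_degree", "n_hubs",
                           "max_degree_gene", "max_degree")])

  report <- structure(
    list(summary = summary, deg_table = deg_table, ordination = ordination,
         enrichment = enr$result, oc_matrix = ct$oc,
         assignment = ct$assignment, superpathways = ct$summary,
         pathway_composition = ct$composition, screen = screen,
         upset = upset, network = net, network_stats = net_stats,
         config = config),
    class = "superpath_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_deg_table(report$deg_table, file.path(dir, "deg.tsv"))
  write_tsv(report$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(report$oc_matrix)) {
    oc_df <- data.frame(pathway_id = rownames(report$oc_matrix),
                        report$oc_matrix, check.names = FALSE)
    write_tsv(oc_df, file.path(dir, "oc_matrix.tsv"))
    write_tsv(data.frame(pathway_id = names(report$assignment$labels),
                         superpathway = unname(report$assignment$labels)),
              file.path(dir, "superpathway_assignment.tsv"))
    summ <- report$superpathways
    summ$genes <- NULL
    write_tsv(summ, file.path(dir, "superpathway_summary.tsv"))
    write_tsv(report$pathway_composition,
              file.path(dir, "pathway_composition.tsv"))
  }
  write_tsv(as.data.frame(report$screen), file.path(dir, "screen.tsv"))
  write_tsv(report$upset, file.path(dir, "upset.tsv"))
  if (!is.null(report$network)) {
    write_tsv(report$network$edges, file.path(dir, "filtered_edges.tsv"))
    write_tsv(data.frame(gene_id = report$network$hubs,
                         degree = report$network$degree[report$network$hubs]),
              file.path(dir, "hubs.tsv"))
  }
  jsonlite::write_json(report$summary, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.superpath_report <- function(x, ...) {
  s <- x$summary
  cat("superpath pipeline report\n")
  cat(sprintf("  genes tested:        %d\n", s$n_genes))
  cat(sprintf("  DEGs (FDR <= %g):    %d (%s%% up)\n",
              x$config$de$fdr_de_threshold, s$n_degs,
              ifelse(is.na(s$pct_up), "-", s$pct_up)))
  cat(sprintf("  strong up / down:    %d / %d\n",
              s$n_strong_up, s$n_strong_down))
  cat(sprintf("  enriched pathways:   %d in %d superpathways\n",
              s$n_enriched_pathways, s$n_superpathways))
  cat(sprintf("  DEG^S / DEG^D / DEG^SD: %d / %d / %d\n",
              s$n_deg_s, s$n_deg_d, s$n_deg_sd))
  cat(sprintf("  PPI: %d nodes, %d edges, mean degree %.2f, %d hubs\n",
              s$n_nodes, s$n_edges, s$mean_degree, s$n_hubs))
  invisible(x)
}

#' @export
summary.superpath_report <- function(object, ...) {
  object$summary
}
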