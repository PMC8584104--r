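#' Read a count matrix and its sample sheet
#'
#' The counts file is a TSV whose first column holds gene identifiers and
#' whose remaining columns are samples; the sample sheet is a TSV with
#' columns `sample_id`, `group` and (optionally) `specimen_type`.
#'
#' @param counts_path,samples_path Input file paths.
#' @return List with `counts` (integer matrix) and `samples`
#'   (`data.frame` aligned with the matrix columns).
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- read_tsv(counts_path)
  if (ncol(df) < 3) stopf("counts file needs a gene column and >= 2 samples")
  gene_ids <- as.character(df[[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0) {
    stopf("duplicated gene row(s) in counts: %s",
          paste(unique(utils::head(dup, 5)), collapse = ", "))
  }
  m <- as.matrix(df[-1])
  rownames(m) <- gene_ids
  storage.mode(m) <- "integer"
  check_count_matrix(m)
  samples <- read_tsv(samples_path)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stopf("sample sheet needs 'sample_id' and 'group' columns")
  }
  if (!setequal(samples$sample_id, colnames(m))) {
    stopf("sample sheet and count matrix disagree on sample ids")
  }
  samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  list(counts = m, samples = samples)
}

#' Write a count matrix and sample sheet
#'
#' @param counts Integer matrix with gene row names.
#' @param samples Sample sheet `data.frame`.
#' @param counts_path,samples_path Output file paths.
#' @return Invisibly, the counts path.
#' @export
write_counts <- function(counts, samples, counts_path, samples_path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(df, counts_path)
  write_tsv(samples, samples_path)
  invisible(counts_path)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then tab-separated member genes.
#'
#' @param path Input file.
#' @return Named list of member character vectors; descriptions are kept
#'   in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    stopf("GMT line(s) with fewer than 3 fields: line %s",
          paste(utils::head(short, 5), collapse = ", "))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stopf("duplicate pathway ids in GMT")
  collection <- lapply(fields, function(f) f[-(1:2)])
  names(collection) <- ids
  attr(collection, "descriptions") <-
    setNames(vapply(fields, `[[`, character(1), 2), ids)
  collection
}

#' Write a pathway collection as GMT
#'
#' @param collection Named list of member vectors.
#' @param path Output file.
#' @param descriptions Optional named descriptions (defaults to the ids).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(collection, "descriptions")
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(names(collection), names(collection))
  }
  lines <- vapply(names(collection), function(id) {
    paste(c(id, descriptions[[id]], collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog map TSV (`source_gene`, `target_gene`)
#' @param path Input file.
#' @return `data.frame` with the two id columns.
#' @export
read_ortholog_map <- function(path) {
  df <- read_tsv(path)
  if (!all(c("source_gene", "target_gene") %in% names(df))) {
    stopf("ortholog map needs 'source_gene' and 'target_gene' columns")
  }
  if (anyDuplicated(df[c("source_gene", "target_gene")])) {
    stopf("ortholog map contains duplicate pairs")
  }
  df
}

#' Read an evidence catalog TSV (`gene_id` + 0/1 channel columns)
#' @param path Input file.
#' @return `data.frame`.
#' @export
read_evidence_catalog <- function(path) {
  df <- read_tsv(path)
  if (!"gene_id" %in% names(df)) stopf("evidence catalog needs 'gene_id'")
  if (anyDuplicated(df$gene_id)) {
    stopf("evidence catalog contains duplicate gene ids")
  }
  channels <- setdiff(names(df), "gene_id")
  for (ch in channels) {
    v <- df[[ch]]
    if (!all(v %in% c(0, 1, TRUE, FALSE))) {
      stopf("evidence channel '%s' must be 0/1", ch)
    }
    df[[ch]] <- as.integer(v)
  }
  df
}

#' Read a PPI edge-list TSV (`gene_a`, `gene_b`, `confidence`)
#' @param path Input file.
#' @return `data.frame`.
#' @export
read_ppi_edges <- function(path) {
  df <- read_tsv(path)
  if (!all(c("gene_a", "gene_b", "confidence") %in% names(df))) {
    stopf("PPI file needs 'gene_a', 'gene_b', 'confidence' columns")
  }
  df$confidence <- as.numeric(df$confidence)
  df
}

#' Write a DEG table as TSV
#' @param deg_table A `deg_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg_table, path) {
  write_tsv(as.data.frame(deg_table), path)
}

#' Read a DEG table written by [write_deg_table()]
#' @param path Input file.
#' @return A `deg_table`.
#' @export
read_deg_table <- function(path) {
  df <- read_tsv(path)
  df$is_deg <- as.logical(df$is_deg)
  class(df) <- c("deg_table", "data.frame")
  df
}
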