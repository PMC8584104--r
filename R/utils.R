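# Internal helpers shared across modules.

# Integer percentage share, rounded to the nearest integer; NA when the
# denominator is zero so callers never divide by zero.
share_pct <- function(part, whole) {
  if (is.na(whole) || whole == 0) return(NA_real_)
  round(100 * part / whole)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_proportion <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stopf("'%s' must be a proportion in [0, 1]", name)
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(!is.na(x)) && all(if (strict) x > 0 else x >= 0)
  if (!ok) stopf("'%s' must be %s", name, if (strict) "positive" else "non-negative")
  invisible(x)
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stopf("counts must have unique gene row names")
  }
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts))) {
    stopf("counts must have unique sample column names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be non-negative integers")
  }
  invisible(counts)
}

# Split a two-level grouping vector into column indices, honouring the
# requested contrast (numerator group first).
group_indices <- function(groups, contrast) {
  groups <- as.character(groups)
  missing_lv <- setdiff(contrast, unique(groups))
  if (length(missing_lv) > 0) {
    stopf("group level(s) not present in 'groups': %s",
          paste(missing_lv, collapse = ", "))
  }
  list(num = which(groups == contrast[1]),
       den = which(groups == contrast[2]))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# Derived per-stage seeds so each generator consumes an independent stream
# of the master seed (kept below 2^31 - 1).
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}
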