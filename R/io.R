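# Reading, writing, filtering and subsampling of tab-delimited expression
# matrices. Two dialects are supported: "plain" (header row of condition
# names, first column gene IDs) and "pcl" (Stanford PCL: NAME/GWEIGHT columns
# and an EWEIGHT row, all ignored on input).

MISSING_TOKENS <- c("", "NA", "nan", "NaN")

#' Read a tab-delimited expression matrix
#'
#' @param path file path.
#' @param dialect `"plain"` or `"pcl"`. In the pcl dialect, columns named
#'   `NAME` or `GWEIGHT` and a row whose identifier is `EWEIGHT` are skipped.
#' @return expression matrix (genes x conditions) with `NA` at missing cells.
#'   Row and column order of the file is preserved.
#' @export
read_matrix <- function(path, dialect = c("plain", "pcl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) < 2L) stop("file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  nf <- length(header)
  body <- fields[-1L]
  bad <- which(lengths(body) != nf)
  if (length(bad))
    stop(sprintf("ragged row: line %d has %d fields, header has %d",
                 bad[1L] + 1L, length(body[[bad[1L]]]), nf))
  keep_col <- rep(TRUE, nf - 1L)
  cond_ids <- header[-1L]
  if (dialect == "pcl") {
    keep_col <- !(toupper(cond_ids) %in% c("NAME", "GWEIGHT"))
    is_eweight <- vapply(body, function(f) toupper(f[1L]) == "EWEIGHT",
                         logical(1))
    body <- body[!is_eweight]
  }
  gene_ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ID: ", gene_ids[duplicated(gene_ids)][1L])
  cells <- do.call(rbind, lapply(body, `[`, -1L))[, keep_col, drop = FALSE]
  vals <- suppressWarnings(
    matrix(ifelse(trimws(cells) %in% MISSING_TOKENS, NA_real_,
                  as.numeric(cells)),
           nrow = length(gene_ids)))
  if (any(is.na(vals) & !(trimws(cells) %in% MISSING_TOKENS)))
    stop("non-numeric value in matrix body")
  dimnames(vals) <- list(gene_ids, cond_ids[keep_col])
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix to a tab-delimited file
#'
#' Missing cells are always written as the token `NA`. Values are printed
#' with 17 significant digits, so a read/write round-trip reproduces them to
#' well beyond 12 significant digits.
#'
#' @param m expression matrix.
#' @param path output path.
#' @param dialect `"plain"` or `"pcl"` (adds a unit GWEIGHT column and a unit
#'   EWEIGHT row).
#' @export
write_matrix <- function(m, path, dialect = c("plain", "pcl")) {
  dialect <- match.arg(dialect)
  validate_expression_matrix(m)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  rows <- apply(m, 1L, function(v) paste(fmt(v), collapse = "\t"))
  if (dialect == "plain") {
    out <- c(paste(c("GID", colnames(m)), collapse = "\t"),
             paste(rownames(m), rows, sep = "\t"))
  } else {
    out <- c(paste(c("GID", "GWEIGHT", colnames(m)), collapse = "\t"),
             paste(c("EWEIGHT", "", rep("1", ncol(m))), collapse = "\t"),
             paste(rownames(m), "1", rows, sep = "\t"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Build a complete (missing-free) reference matrix
#'
#' Two-stage filter: conditions whose missing count exceeds
#' `max_mv_per_condition` are dropped first (skipped when `NULL`), then every
#' gene with at least one remaining missing value is dropped. Ordering of the
#' retained rows and columns is preserved and no value is altered.
#'
#' @param m expression matrix.
#' @param max_mv_per_condition non-negative integer threshold, or `NULL` to
#'   skip the condition filter.
#' @return complete expression matrix.
#' @export
build_reference_matrix <- function(m, max_mv_per_condition = NULL) {
  validate_expression_matrix(m)
  if (!is.null(max_mv_per_condition)) {
    if (max_mv_per_condition < 0) stop("max_mv_per_condition must be >= 0")
    m <- m[, colSums(is.na(m)) <= max_mv_per_condition, drop = FALSE]
    if (ncol(m) < 2L) stop("fewer than 2 conditions remain after filtering")
  }
  m <- m[rowSums(is.na(m)) == 0L, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 genes remain after filtering")
  m
}

#' Subsample genes uniformly without replacement
#'
#' Samples `round(fraction * G)` genes (half away from zero) and returns them
#' in their original row order. Deterministic given `seed`.
#'
#' @param m expression matrix.
#' @param fraction fraction of genes to keep, in (0, 1].
#' @param seed integer seed.
#' @export
subsample_genes <- function(m, fraction, seed) {
  validate_expression_matrix(m)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  size <- round_half_away(fraction * nrow(m))
  if (size < 2L) stop("fraction * G must be at least 2")
  idx <- with_seed(seed, sample.int(nrow(m), size))
  m[sort(idx), , drop = FALSE]
}
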