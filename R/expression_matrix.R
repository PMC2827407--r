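#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2-ratios with genes
#' as rows and experimental conditions as columns; missing values are `NA`.
#' Row and column names carry the gene and condition identifiers and must be
#' unique and non-empty. At least 2 genes and 2 conditions are required, and
#' every non-missing value must be finite.
#'
#' @param m numeric matrix with dimnames.
#' @param require_complete if `TRUE`, additionally require zero missing cells.
#' @return `m`, invisibly; errors describe the first violated invariant.
#' @export
validate_expression_matrix <- function(m, require_complete = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression matrix must be a numeric matrix")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("expression matrix needs at least 2 genes and 2 conditions")
  gid <- rownames(m); cid <- colnames(m)
  if (is.null(gid) || is.null(cid) || any(!nzchar(gid)) || any(!nzchar(cid)))
    stop("gene and condition identifiers must be present and non-empty")
  if (anyDuplicated(gid)) stop("duplicate gene identifiers")
  if (anyDuplicated(cid)) stop("duplicate condition identifiers")
  obs <- !is.na(m)
  if (!all(obs)) {
    if (!any(obs)) stop("matrix has no observed values")
    if (require_complete) stop("matrix contains missing values")
  }
  if (any(!is.finite(m[obs])))
    stop("non-missing values must be finite")
  invisible(m)
}

#' Construct an expression matrix from values and identifiers
#'
#' @param values numeric matrix (genes x conditions); `NA` marks missing.
#' @param gene_ids,condition_ids character vectors of unique identifiers;
#'   default to existing dimnames or `g1..gG` / `c1..cn`.
#' @return validated numeric matrix with dimnames.
#' @export
expression_matrix <- function(values, gene_ids = NULL, condition_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  usable <- function(ids) if (is.null(ids) || any(!nzchar(ids))) NULL else ids
  if (is.null(gene_ids))
    gene_ids <- usable(rownames(values)) %||% paste0("g", seq_len(nrow(values)))
  if (is.null(condition_ids))
    condition_ids <- usable(colnames(values)) %||%
      paste0("c", seq_len(ncol(values)))
  dimnames(values) <- list(gene_ids, condition_ids)
  validate_expression_matrix(values)
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a
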