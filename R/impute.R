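# Imputation front end: method registry, shared fallback chain and the
# imputation_result container. Every method estimates each masked entry; an
# estimate a method cannot define (no qualified neighbour, empty row, ...)
# falls through the chain: gene observed mean -> condition observed mean ->
# global observed mean -> 0, with counts recorded for audit.

IMPUTATION_METHODS <- c("row_mean", "knn", "sknn", "llsi", "lsi_gene",
                        "lsi_array", "lsi_combined", "lsi_adaptive",
                        "em_gene", "em_array")

METHOD_ALIASES <- c(row_average = "row_mean", lsi_adaptative = "lsi_adaptive")

# Fallback value and level for every masked entry.
fallback_values <- function(data) {
  X <- masked_matrix(data)
  gm <- rowMeans(X, na.rm = TRUE)
  cm <- colMeans(X, na.rm = TRUE)
  gl <- mean(X, na.rm = TRUE)
  g <- data$mask[, 1L]; j <- data$mask[, 2L]
  val <- gm[g]; lev <- rep("gene_mean", nrow(data$mask))
  miss <- !is.finite(val)
  val[miss] <- cm[j[miss]]; lev[miss] <- "condition_mean"
  miss <- !is.finite(val)
  val[miss] <- gl; lev[miss] <- "global_mean"
  miss <- !is.finite(val)
  val[miss] <- 0; lev[miss] <- "zero"
  list(values = unname(val), level = lev)
}

finish_result <- function(data, estimates, method, params = list()) {
  estimates <- as.numeric(estimates)
  stopifnot(length(estimates) == nrow(data$mask))
  und <- !is.finite(estimates)
  counts <- c(method = sum(!und), gene_mean = 0, condition_mean = 0,
              global_mean = 0, zero = 0)
  if (any(und)) {
    fb <- fallback_values(data)
    estimates[und] <- fb$values[und]
    tab <- table(fb$level[und])
    counts[names(tab)] <- tab
  }
  completed <- masked_matrix(data)
  if (nrow(data$mask)) completed[data$mask] <- estimates
  params$fallback <- counts
  structure(list(completed = completed, estimates = estimates,
                 mask = data$mask, method = method, params = params),
            class = "imputation_result")
}

#' Impute the masked entries of a dataset
#'
#' Dispatches to one of the registered replacement methods: `row_mean`
#' (alias `row_average`), `knn`, `sknn`, `llsi`, `lsi_gene`, `lsi_array`,
#' `lsi_combined`, `lsi_adaptive` (alias `lsi_adaptative`), `em_gene`,
#' `em_array`. The name `bpca` is reserved as a plugin hook and raises a
#' not-implemented error. Every method leaves unmasked entries untouched and
#' returns a finite estimate for every masked entry, using the fallback
#' chain (gene mean, condition mean, global mean, 0) where its own estimate
#' is undefined.
#'
#' @param data a `masked_dataset`.
#' @param method method name (see above).
#' @param ... hyperparameters forwarded to the method (`k`, `K`, `p`,
#'   `bins`, `tol`, `max_iter`, `cv_fraction`, `seed`).
#' @return an `imputation_result`: list with `completed` (complete matrix),
#'   `estimates` (one per mask row), `mask`, `method` and `params`
#'   (hyperparameters, convergence info, fallback counts).
#' @export
impute <- function(data, method, ...) {
  if (!inherits(data, "masked_dataset")) stop("data must be a masked_dataset")
  method <- as.character(method)[1L]
  if (method %in% names(METHOD_ALIASES)) method <- METHOD_ALIASES[[method]]
  if (identical(method, "bpca"))
    stop("bpca is a plugin hook and is not implemented")
  fn <- switch(method,
    row_mean = impute_row_mean,
    knn = impute_knn,
    sknn = impute_sknn,
    llsi = impute_llsi,
    lsi_gene = impute_lsi_gene,
    lsi_array = impute_lsi_array,
    lsi_combined = impute_lsi_combined,
    lsi_adaptive = impute_lsi_adaptive,
    em_gene = impute_em_gene,
    em_array = impute_em_array,
    stop("unknown imputation method: ", method))
  fn(data, ...)
}

#' @export
print.imputation_result <- function(x, ...) {
  fb <- x$params$fallback
  cat(sprintf("Imputation result: method %s, %d estimates (%d by fallback)\n",
              x$method, length(x$estimates),
              if (is.null(fb)) 0L else sum(fb[-1L])))
  invisible(x)
}

# Secondary masking for internal cross-validation: hides cv_fraction of the
# OBSERVED entries on top of the primary mask. Returns the combined dataset
# and the row indices of the secondary entries within its mask.
secondary_mask <- function(data, cv_fraction, seed, min_entries = 10) {
  G <- nrow(data$reference); n <- ncol(data$reference)
  obs <- setdiff(seq_len(G * n), linear_index(data$mask, G))
  n2 <- round_half_away(cv_fraction * length(obs))
  if (n2 < min_entries)
    stop("cv_fraction masks fewer than ", min_entries, " entries")
  sec <- sort(with_seed(seed, sample(obs, n2)))
  mask2 <- rbind(data$mask, arrayInd(sec, c(G, n)))
  d2 <- new_masked_dataset(data$reference, mask2, data$tau, data$scope, seed)
  list(data = d2, secondary = nrow(data$mask) + seq_len(n2))
}

# Mix gene-space and array-space estimates. At the exact boundaries the
# constituent is returned as-is; in between, an entry missing on one side
# uses the other side alone.
mix_estimates <- function(eg, ea, p) {
  if (length(p) == 1L) p <- rep(p, length(eg))
  out <- p * eg + (1 - p) * ea
  out[p == 1] <- eg[p == 1]
  out[p == 0] <- ea[p == 0]
  only_a <- is.na(eg) & !is.na(ea) & p > 0 & p < 1
  only_g <- !is.na(eg) & is.na(ea) & p > 0 & p < 1
  out[only_a] <- ea[only_a]
  out[only_g] <- eg[only_g]
  out
}

# RMSE of a p-mixture on a subset of entries, NA estimates filled by the
# fallback chain of the CV dataset (mirrors the final pipeline).
grid_search_p <- function(eg, ea, truth, fill, subset, grid = seq(0, 1, 0.01)) {
  err <- vapply(grid, function(p) {
    est <- mix_estimates(eg, ea, p)
    est[!is.finite(est)] <- fill[!is.finite(est)]
    sqrt(mean((est[subset] - truth[subset])^2))
  }, numeric(1))
  grid[which.min(err)]
}
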