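# Scoring of imputation accuracy: RMSE on the held-out true values,
# predicted-vs-true correlation, and pairwise method win rates.

#' Root mean square error of an imputation
#'
#' `sqrt(mean((estimate - truth)^2))` over the masked entries, on the
#' log2-ratio scale of the data (unnormalized). `normalized = TRUE` divides
#' by the standard deviation of the true values for cross-literature
#' comparison.
#'
#' @param result an `imputation_result`.
#' @param data the `masked_dataset` it was computed from.
#' @param normalized divide by `sd(truth)` (default off).
#' @return non-negative real.
#' @export
rmse <- function(result, data, normalized = FALSE) {
  if (nrow(data$mask) == 0L) stop("RMSE is undefined for an empty mask")
  if (length(result$estimates) != nrow(data$mask))
    stop("estimates do not cover the mask")
  out <- sqrt(mean((result$estimates - data$truth)^2))
  if (normalized) out <- out / stats::sd(data$truth)
  out
}

#' Correlation between imputed and true values
#'
#' Pearson correlation over the masked entries. If either side has zero
#' variance the correlation is undefined and `NA` is returned (flagged, not
#' an error).
#'
#' @param result an `imputation_result`.
#' @param data the `masked_dataset` it was computed from.
#' @return correlation in \[-1, 1\], or `NA` when degenerate.
#' @export
predicted_true_correlation <- function(result, data) {
  if (nrow(data$mask) < 3L) stop("correlation needs at least 3 masked entries")
  if (stats::sd(result$estimates) == 0 || stats::sd(data$truth) == 0)
    return(NA_real_)
  stats::cor(result$estimates, data$truth)
}

#' Pairwise win matrix over paired simulations
#'
#' Cell (A, B) is the percentage of simulations in which method A achieved a
#' strictly smaller RMSE than method B on the identical mask; exact ties
#' contribute half a win to each side, so `cell(A,B) + cell(B,A) = 100`.
#'
#' @param records data frame with columns `method`, `tau`, `replicate`,
#'   `rmse` (a `scope`/`dataset` column, if present, joins the simulation
#'   key). Every method must cover the same simulation set.
#' @return square matrix of percentages with `NA` diagonal.
#' @export
pairwise_win_matrix <- function(records) {
  records <- as.data.frame(records)
  keycols <- intersect(c("dataset", "scope", "tau", "replicate"),
                       names(records))
  key <- do.call(paste, c(records[keycols], sep = "\r"))
  methods <- unique(records$method)
  sims <- sort(unique(key))
  rm_mat <- matrix(NA_real_, length(sims), length(methods),
                   dimnames = list(sims, methods))
  rm_mat[cbind(match(key, sims), match(records$method, methods))] <-
    records$rmse
  if (anyNA(rm_mat))
    stop("methods were not evaluated on identical simulation sets")
  W <- matrix(NA_real_, length(methods), length(methods),
              dimnames = list(methods, methods))
  for (a in seq_along(methods)) for (b in seq_along(methods)) {
    if (a == b) next
    W[a, b] <- 100 * mean((rm_mat[, a] < rm_mat[, b]) +
                            0.5 * (rm_mat[, a] == rm_mat[, b]))
  }
  W
}
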