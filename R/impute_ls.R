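# Least-squares replacement methods in gene space (regression on correlated
# genes), array space (multivariate-normal conditional expectation across
# conditions), and their global / per-entry adaptive mixtures.

# Gene-space estimates with the per-entry maximum |Pearson r| among the
# selected neighbours (needed by the adaptive mixture).
lsi_gene_estimates <- function(data, K = 10) {
  X <- masked_matrix(data)
  G <- nrow(X); n <- ncol(X)
  W <- 1 * !is.na(X)
  X0 <- X; X0[is.na(X)] <- 0
  est <- rep(NA_real_, nrow(data$mask))
  rmax <- rep(NA_real_, nrow(data$mask))
  idx_all <- seq_len(G)
  for (g in unique(data$mask[, 1L])) {
    og <- W[g, ]
    Mg <- sweep(W, 2L, og, "*")       # mutual observation indicator
    ngh <- rowSums(Mg)
    xg0 <- X0[g, ]
    HM <- X0 * Mg
    sum_h <- rowSums(HM)
    sum_g <- as.vector(Mg %*% xg0)
    sum_hh <- rowSums(HM * X0)
    sum_gg <- as.vector(Mg %*% (xg0^2))
    sum_gh <- as.vector(HM %*% xg0)
    mean_h <- sum_h / ngh
    mean_g <- sum_g / ngh
    var_h <- sum_hh / ngh - mean_h^2
    var_g <- sum_gg / ngh - mean_g^2
    covar <- sum_gh / ngh - mean_h * mean_g
    r <- covar / sqrt(pmax(var_h, 0) * pmax(var_g, 0))
    ok <- idx_all != g & ngh >= 3 & is.finite(r) &
      var_h > 1e-12 & var_g > 1e-12
    rows <- which(data$mask[, 1L] == g)
    for (i in rows) {
      j <- data$mask[i, 2L]
      elig <- which(ok & W[, j] > 0)
      if (!length(elig)) next
      sel <- elig[order(-abs(r[elig]), elig)][seq_len(min(K, length(elig)))]
      preds <- mean_g[sel] + (covar[sel] / var_h[sel]) * (X[sel, j] - mean_h[sel])
      w <- (r[sel]^2 / (1 - r[sel]^2 + 1e-6))^2
      est[i] <- sum(w * preds) / sum(w)
      rmax[i] <- abs(r[sel][1L])
    }
  }
  list(estimates = est, rmax = rmax)
}

#' Gene-space least-squares imputation (LSI_gene)
#'
#' For a masked entry (g, j), the K genes observed at j with the largest
#' absolute Pearson correlation to g (over at least 3 mutually observed
#' coordinates) each predict the entry through a simple linear regression of
#' g on the neighbour; the predictions are combined with weights
#' `(r^2 / (1 - r^2 + 1e-6))^2`, so near-perfect correlations dominate.
#' Candidates with undefined correlation (constant over the shared
#' coordinates) are disqualified.
#'
#' @param data a `masked_dataset`.
#' @param K neighbour count (default 10).
#' @return an `imputation_result`.
#' @export
impute_lsi_gene <- function(data, K = 10) {
  if (K < 1) stop("K must be >= 1")
  lg <- lsi_gene_estimates(data, K)
  finish_result(data, lg$estimates, "lsi_gene", list(K = K))
}

lsi_array_estimates <- function(data, ridge = 1e-8) {
  X <- masked_matrix(data)
  complete <- which(rowSums(is.na(X)) == 0L)
  est <- rep(NA_real_, nrow(data$mask))
  if (length(complete) < 2L) return(est)
  mu <- colMeans(X[complete, , drop = FALSE])
  S <- stats::cov(X[complete, , drop = FALSE])
  filled <- conditional_fill(X, mu, S, ridge)
  if (nrow(data$mask)) est <- filled[data$mask]
  est
}

# Fill the missing cells of X with the multivariate-normal conditional
# expectation mu_M + S_MO S_OO^-1 (x_O - mu_O), grouped by missing pattern.
conditional_fill <- function(X, mu, S, ridge) {
  mis <- is.na(X)
  if (!any(mis)) return(X)
  key <- apply(mis, 1L, paste, collapse = "")
  for (rows in split(which(rowSums(mis) > 0L), key[rowSums(mis) > 0L])) {
    M <- which(mis[rows[1L], ])
    O <- which(!mis[rows[1L], ])
    if (!length(O)) {
      X[rows, M] <- rep(mu[M], each = length(rows))
      next
    }
    SOO <- S[O, O, drop = FALSE]
    diag(SOO) <- diag(SOO) + ridge
    B <- S[M, O, drop = FALSE] %*% solve(SOO)
    dev <- sweep(X[rows, O, drop = FALSE], 2L, mu[O])
    X[rows, M] <- rep(mu[M], each = length(rows)) + dev %*% t(B)
  }
  X
}

#' Array-space least-squares imputation (LSI_array)
#'
#' Single pass: the condition mean vector and condition covariance are
#' estimated from the complete genes only (with a 1e-8 ridge on the diagonal
#' when solving), and each incomplete gene's missing coordinates are the
#' multivariate-normal conditional expectation given its observed
#' coordinates. Requires at least 2 complete genes, otherwise every estimate
#' falls through the fallback chain.
#'
#' @param data a `masked_dataset`.
#' @return an `imputation_result`.
#' @export
impute_lsi_array <- function(data) {
  finish_result(data, lsi_array_estimates(data), "lsi_array")
}

#' Global mixture of gene- and array-space estimates (LSI_combined)
#'
#' Final estimate = `p * gene + (1 - p) * array` for every masked entry.
#' `p = "auto"` hides `cv_fraction` of the observed entries and grid-searches
#' p over \{0, 0.01, ..., 1\} to minimise RMSE on the hidden entries; the
#' chosen p is recorded in `params`. At the boundaries p = 1 / p = 0 the
#' result is exactly the gene / array constituent.
#'
#' @param data a `masked_dataset`.
#' @param p mixing weight in \[0, 1\] or `"auto"`.
#' @param cv_fraction,seed secondary-masking controls for `p = "auto"`.
#' @param K gene-space neighbour count.
#' @return an `imputation_result`.
#' @export
impute_lsi_combined <- function(data, p = "auto", cv_fraction = 0.05,
                                seed = 1, K = 10) {
  params <- list(K = K)
  if (nrow(data$mask) == 0L)
    return(finish_result(data, numeric(0), "lsi_combined", params))
  if (identical(p, "auto")) {
    cv <- secondary_mask(data, cv_fraction, seed)
    eg2 <- lsi_gene_estimates(cv$data, K)$estimates
    ea2 <- lsi_array_estimates(cv$data)
    fill <- fallback_values(cv$data)$values
    p <- grid_search_p(eg2, ea2, cv$data$truth, fill, cv$secondary)
    params$p_auto <- TRUE
  }
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  params$p <- p
  eg <- lsi_gene_estimates(data, K)$estimates
  ea <- lsi_array_estimates(data)
  finish_result(data, mix_estimates(eg, ea, p), "lsi_combined", params)
}

#' Per-entry adaptive mixture (LSI_adaptive)
#'
#' As [impute_lsi_combined()], but the mixing weight varies per masked
#' entry: entries are bucketed by r_max — the largest absolute Pearson
#' correlation among the entry's gene-space neighbours — into `bins`
#' equal-width bins on \[0, 1\] (entries with no qualified neighbour join the
#' lowest bin), and each bin's p is grid-searched on its own secondary-mask
#' entries. Bins holding fewer than 20 secondary entries inherit the global
#' p. All per-bin weights are recorded in `params$p_bins`.
#'
#' @param data a `masked_dataset`.
#' @param bins number of r_max bins (default 10); `bins = 1` reduces to the
#'   global mixture.
#' @param cv_fraction,seed secondary-masking controls.
#' @param K gene-space neighbour count.
#' @return an `imputation_result`.
#' @export
impute_lsi_adaptive <- function(data, bins = 10, cv_fraction = 0.05,
                                seed = 1, K = 10) {
  if (bins < 1) stop("bins must be >= 1")
  if (nrow(data$mask) == 0L)
    return(finish_result(data, numeric(0), "lsi_adaptive",
                         list(K = K, bins = bins)))
  bin_of <- function(r) {
    b <- pmin(bins, floor(r * bins) + 1L)
    b[!is.finite(r)] <- 1L
    b
  }
  cv <- secondary_mask(data, cv_fraction, seed)
  lg2 <- lsi_gene_estimates(cv$data, K)
  ea2 <- lsi_array_estimates(cv$data)
  fill <- fallback_values(cv$data)$values
  p_global <- grid_search_p(lg2$estimates, ea2, cv$data$truth, fill,
                            cv$secondary)
  sec_bins <- bin_of(lg2$rmax[cv$secondary])
  p_bins <- rep(p_global, bins)
  for (b in seq_len(bins)) {
    in_b <- cv$secondary[sec_bins == b]
    if (length(in_b) >= 20)
      p_bins[b] <- grid_search_p(lg2$estimates, ea2, cv$data$truth, fill, in_b)
  }
  lg <- lsi_gene_estimates(data, K)
  ea <- lsi_array_estimates(data)
  p_entry <- p_bins[bin_of(lg$rmax)]
  finish_result(data, mix_estimates(lg$estimates, ea, p_entry),
                "lsi_adaptive",
                list(K = K, bins = bins, p_global = p_global,
                     p_bins = p_bins))
}
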