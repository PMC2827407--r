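# Expectation-maximisation imputation for a multivariate normal model.
# em_array treats the n conditions as variables and the genes as
# observations; em_gene runs the same machinery per incomplete gene in the
# small space spanned by the gene and its most-correlated neighbours.

# Classical EM for MVN data with missing entries. Rows are observations,
# columns variables. Missing cells are initialised by row means (global mean
# for all-missing rows); each E-step computes conditional expectations and
# conditional covariances per missing pattern, the M-step updates (mu,
# Sigma) with the conditional-covariance correction (MLE, 1/N). The
# observed-data log-likelihood is evaluated with the parameters entering
# each E-step, so the recorded trace is non-decreasing.
em_core <- function(X, tol = 1e-6, max_iter = 300,
                    ridge_solve = 1e-8, ridge_sigma = 0) {
  N <- nrow(X); n <- ncol(X)
  mis <- is.na(X)
  glob <- mean(X, na.rm = TRUE)
  init <- rowMeans(X, na.rm = TRUE)
  init[!is.finite(init)] <- glob
  Xc <- X
  for (i in which(rowSums(mis) > 0L)) Xc[i, mis[i, ]] <- init[i]
  mu <- colMeans(Xc)
  Sigma <- crossprod(sweep(Xc, 2L, mu)) / N
  if (ridge_sigma > 0) diag(Sigma) <- diag(Sigma) + ridge_sigma
  key <- apply(mis, 1L, paste, collapse = "")
  groups <- split(seq_len(N), key)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  e_step <- function(mu, Sigma) {
    Xhat <- X
    Ctot <- matrix(0, n, n)
    ll <- 0
    for (rows in groups) {
      M <- which(mis[rows[1L], ])
      O <- which(!mis[rows[1L], ])
      if (!length(O)) {
        Xhat[rows, M] <- rep(mu[M], each = length(rows))
        Ctot[M, M] <- Ctot[M, M] + length(rows) * Sigma[M, M]
        next
      }
      SOO <- Sigma[O, O, drop = FALSE]
      diag(SOO) <- diag(SOO) + ridge_solve
      SOOinv <- solve(SOO)
      dev <- sweep(X[rows, O, drop = FALSE], 2L, mu[O])
      quad <- rowSums((dev %*% SOOinv) * dev)
      ll <- ll - 0.5 * sum(length(O) * log(2 * pi) +
                             as.numeric(determinant(SOO)$modulus) + quad)
      if (length(M)) {
        B <- Sigma[M, O, drop = FALSE] %*% SOOinv
        Xhat[rows, M] <- rep(mu[M], each = length(rows)) + dev %*% t(B)
        Cpat <- Sigma[M, M, drop = FALSE] - B %*% Sigma[O, M, drop = FALSE]
        Ctot[M, M] <- Ctot[M, M] + length(rows) * Cpat
      }
    }
    list(Xhat = Xhat, Ctot = Ctot, ll = ll)
  }
  if (any(mis)) {
    for (iter in seq_len(max_iter)) {
      es <- e_step(mu, Sigma)
      loglik <- c(loglik, es$ll)
      mu_new <- colMeans(es$Xhat)
      Sigma_new <- (crossprod(sweep(es$Xhat, 2L, mu_new)) + es$Ctot) / N
      if (ridge_sigma > 0) diag(Sigma_new) <- diag(Sigma_new) + ridge_sigma
      delta <- max(abs(c(mu_new - mu, Sigma_new - Sigma))) /
        max(1, max(abs(c(mu, Sigma))))
      mu <- mu_new; Sigma <- Sigma_new
      if (delta < tol) { converged <- TRUE; break }
    }
    Xhat <- e_step(mu, Sigma)$Xhat
  } else {
    loglik <- e_step(mu, Sigma)$ll
    Xhat <- X
    converged <- TRUE
  }
  list(Xhat = Xhat, mu = mu, Sigma = Sigma, iterations = iter,
       converged = converged, loglik = loglik)
}

#' EM imputation in array space (EM_array)
#'
#' Fits a multivariate normal over the n conditions (genes as observations)
#' by expectation-maximisation: missing cells are initialised by row means,
#' the E-step computes per-gene conditional expectations and conditional
#' covariances of the missing coordinates, and the M-step updates the mean
#' and covariance including the conditional-covariance correction. Estimates
#' are the conditional expectations under the final parameters. The
#' observed-data log-likelihood trace is recorded in `params$loglik` and is
#' non-decreasing.
#'
#' @param data a `masked_dataset` with at most 64 conditions.
#' @param tol relative-change convergence tolerance on (mu, Sigma).
#' @param max_iter iteration cap; non-convergence yields a warning and
#'   `params$converged = FALSE`, not an error.
#' @return an `imputation_result`.
#' @export
impute_em_array <- function(data, tol = 1e-6, max_iter = 300) {
  if (ncol(data$reference) > 64) stop("em_array supports at most 64 conditions")
  X <- masked_matrix(data)
  fit <- em_core(X, tol, max_iter, ridge_solve = 1e-8)
  if (!fit$converged)
    warning("em_array did not converge in ", max_iter, " iterations")
  est <- if (nrow(data$mask)) fit$Xhat[data$mask] else numeric(0)
  finish_result(data, est, "em_array",
                list(iterations = fit$iterations, converged = fit$converged,
                     loglik = fit$loglik))
}

#' EM imputation in gene space (EM_gene)
#'
#' Gene-space analogue restricted to neighbourhoods: for each incomplete
#' gene g, the K genes most correlated with g (|Pearson r| over at least 3
#' mutually observed coordinates) and g itself form a (K+1)-variable system
#' with the conditions as observations; the same EM machinery runs in that
#' small space with a 1e-6 ridge (the system is typically rank-deficient
#' when K + 1 exceeds the condition count), and g's missing values take its
#' conditional expectations. Genes with no qualified neighbour fall through
#' the fallback chain.
#'
#' @param data a `masked_dataset`.
#' @param K neighbour count (default 10).
#' @param tol,max_iter EM controls as in [impute_em_array()].
#' @return an `imputation_result`.
#' @export
impute_em_gene <- function(data, K = 10, tol = 1e-6, max_iter = 300) {
  if (K < 1) stop("K must be >= 1")
  X <- masked_matrix(data)
  G <- nrow(X)
  mask_lin <- linear_index(data$mask, G)
  W <- 1 * !is.na(X)
  nobs <- tcrossprod(W)
  C <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
  C[nobs < 3] <- NA
  diag(C) <- NA
  est <- rep(NA_real_, nrow(data$mask))
  iters <- integer(0)
  for (g in unique(data$mask[, 1L])) {
    r <- abs(C[g, ])
    cand <- which(is.finite(r))
    mj <- which(is.na(X[g, ]))
    if (!length(cand)) next
    sel <- cand[order(-r[cand], cand)][seq_len(min(K, length(cand)))]
    sub <- t(X[c(g, sel), , drop = FALSE])
    fit <- em_core(sub, tol, max_iter,
                   ridge_solve = 1e-6, ridge_sigma = 1e-6)
    iters <- c(iters, fit$iterations)
    est[match((mj - 1L) * G + g, mask_lin)] <- fit$Xhat[mj, 1L]
  }
  finish_result(data, est, "em_gene",
                list(K = K, mean_iterations = if (length(iters)) mean(iters) else NA))
}
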