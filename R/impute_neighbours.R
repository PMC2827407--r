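# Neighbour-based replacement methods: row mean, weighted k-nearest
# neighbours, sequential kNN, and local least squares.

#' Row-mean imputation
#'
#' Each masked entry of gene g is estimated by the arithmetic mean of g's
#' observed values (the classical Row Mean / Row Average method).
#'
#' @param data a `masked_dataset`.
#' @return an `imputation_result`.
#' @export
impute_row_mean <- function(data) {
  X <- masked_matrix(data)
  gm <- rowMeans(X, na.rm = TRUE)
  est <- gm[data$mask[, 1L]]
  est[is.nan(est)] <- NA_real_
  finish_result(data, est, "row_mean")
}

#' Weighted k-nearest-neighbour imputation
#'
#' For a masked entry (g, j), candidate donors are the genes observed at
#' condition j that share at least one observed coordinate with g. Distances
#' are the masked Euclidean d* over mutually observed coordinates; the k
#' nearest donors contribute a weighted mean of their j-values with weights
#' 1/(d* + 1e-9), so an exact duplicate dominates. Fewer than k candidates:
#' all are used.
#'
#' @param data a `masked_dataset`.
#' @param k number of neighbours (default 15; see [select_k_opt()]).
#' @return an `imputation_result`.
#' @export
impute_knn <- function(data, k = 15) {
  if (k < 1) stop("k must be >= 1")
  X <- masked_matrix(data)
  core <- masked_distance_core(X)
  W <- !is.na(X)
  est <- rep(NA_real_, nrow(data$mask))
  for (i in seq_len(nrow(data$mask))) {
    g <- data$mask[i, 1L]; j <- data$mask[i, 2L]
    cand <- which(W[, j] & core$nobs[g, ] >= 1)
    cand <- cand[cand != g]
    if (!length(cand)) next
    d <- core$D[g, cand]
    sel <- order(d, cand)[seq_len(min(k, length(cand)))]
    wts <- 1 / (d[sel] + 1e-9)
    est[i] <- sum(wts * X[cand[sel], j]) / sum(wts)
  }
  finish_result(data, est, "knn", list(k = k))
}

#' Choose k for kNN by secondary masking
#'
#' Hides `cv_fraction` of the observed entries, imputes them by kNN with
#' each candidate k, and returns the k with the smallest RMSE on the hidden
#' entries (ties go to the smallest k). Deterministic given `seed`.
#'
#' @param data a `masked_dataset`.
#' @param candidates integer vector of k values to try.
#' @param cv_fraction fraction of observed entries to hide (default 0.05);
#'   must hide at least 10 entries.
#' @param seed integer seed.
#' @return the selected k.
#' @export
select_k_opt <- function(data, candidates = c(1, 5, 10, 15, 20),
                         cv_fraction = 0.05, seed = 1) {
  if (!length(candidates)) stop("candidates must be non-empty")
  candidates <- sort(unique(as.integer(candidates)))
  cv <- secondary_mask(data, cv_fraction, seed)
  truth <- cv$data$truth[cv$secondary]
  err <- vapply(candidates, function(k) {
    res <- impute_knn(cv$data, k)
    sqrt(mean((res$estimates[cv$secondary] - truth)^2))
  }, numeric(1))
  candidates[which.min(err)]
}

#' Sequential kNN imputation
#'
#' Genes are processed in order of ascending missing count (ties by row
#' index). Genes without missing values form the initial donor pool; each
#' incomplete gene is imputed by the kNN rule against the current pool, then
#' appended to it, so later genes may borrow earlier imputed values. If no
#' complete gene exists, the least-missing gene is seeded by row mean
#' (recorded in `params$seeded_by_row_mean`).
#'
#' @param data a `masked_dataset`.
#' @param k number of neighbours.
#' @return an `imputation_result`.
#' @export
impute_sknn <- function(data, k = 15) {
  if (k < 1) stop("k must be >= 1")
  X <- masked_matrix(data)
  G <- nrow(X); n <- ncol(X)
  mask_lin <- linear_index(data$mask, G)
  est <- rep(NA_real_, nrow(data$mask))
  miss_cnt <- rowSums(is.na(X))
  ord <- order(miss_cnt, seq_len(G))
  pool <- which(miss_cnt == 0L)
  Xc <- X
  seeded <- FALSE
  if (!length(pool)) {
    g0 <- ord[1L]
    fill <- mean(X[g0, ], na.rm = TRUE)
    if (!is.finite(fill)) fill <- mean(X, na.rm = TRUE)
    if (!is.finite(fill)) fill <- 0
    mj <- which(is.na(X[g0, ]))
    Xc[g0, mj] <- fill
    est[match((mj - 1L) * G + g0, mask_lin)] <- fill
    pool <- g0
    seeded <- TRUE
  }
  todo <- ord[miss_cnt[ord] > 0L]
  todo <- setdiff(todo, pool)
  for (g in todo) {
    og <- !is.na(X[g, ])
    mj <- which(!og)
    if (any(og)) {
      P <- Xc[pool, , drop = FALSE]
      dv <- sqrt(n / sum(og) *
                   rowSums(sweep(P[, og, drop = FALSE], 2L, X[g, og])^2))
      sel <- order(dv, pool)[seq_len(min(k, length(pool)))]
      wts <- 1 / (dv[sel] + 1e-9)
      vals <- as.vector(crossprod(P[sel, mj, drop = FALSE], wts)) / sum(wts)
    } else {
      vals <- rep(NA_real_, length(mj))
    }
    est[match((mj - 1L) * G + g, mask_lin)] <- vals
    filled <- vals
    filled[!is.finite(filled)] <- mean(X, na.rm = TRUE)
    Xc[g, mj] <- filled
    pool <- c(pool, g)
  }
  finish_result(data, est, "sknn", list(k = k, seeded_by_row_mean = seeded))
}

llsi_estimates <- function(data, k) {
  X <- masked_matrix(data)
  G <- nrow(X); n <- ncol(X)
  mask_lin <- linear_index(data$mask, G)
  est <- rep(NA_real_, nrow(data$mask))
  complete <- which(rowSums(is.na(X)) == 0L)
  for (g in unique(data$mask[, 1L])) {
    og <- !is.na(X[g, ])
    mj <- which(!og)
    cand <- setdiff(complete, g)
    if (!length(cand) || !any(og)) next
    dv <- sqrt(n / sum(og) *
                 rowSums(sweep(X[cand, og, drop = FALSE], 2L, X[g, og])^2))
    sel <- cand[order(dv, cand)[seq_len(min(k, length(cand)))]]
    A <- X[sel, og, drop = FALSE]       # neighbours on observed coords
    B <- X[sel, mj, drop = FALSE]       # neighbours on missing coords
    x <- pinv(t(A)) %*% X[g, og]
    est[match((mj - 1L) * G + g, mask_lin)] <- as.vector(crossprod(B, x))
  }
  est
}

#' Local least squares imputation (LLSI)
#'
#' For each incomplete gene g, the k complete genes nearest to g over g's
#' observed coordinates are regressors: the least-squares problem
#' `t(A) x ~ w` (A = neighbours on observed coords, w = g's observed values)
#' is solved by pseudoinverse and the missing coordinates are predicted as
#' `t(B) x`. `k = "auto"` picks k from \{5, 10, 15, 20\} (capped at the
#' available neighbours) by secondary-masking cross-validation.
#'
#' @param data a `masked_dataset`.
#' @param k neighbour count or `"auto"`.
#' @param cv_fraction,seed secondary-masking controls for `k = "auto"`.
#' @return an `imputation_result`.
#' @export
impute_llsi <- function(data, k = "auto", cv_fraction = 0.05, seed = 1) {
  params <- list()
  if (nrow(data$mask) == 0L)
    return(finish_result(data, numeric(0), "llsi", list(k = NA)))
  if (identical(k, "auto")) {
    cv <- secondary_mask(data, cv_fraction, seed)
    truth <- cv$data$truth[cv$secondary]
    cands <- c(5L, 10L, 15L, 20L)
    err <- vapply(cands, function(kk) {
      e <- llsi_estimates(cv$data, kk)[cv$secondary]
      fb <- fallback_values(cv$data)$values[cv$secondary]
      e[!is.finite(e)] <- fb[!is.finite(e)]
      sqrt(mean((e - truth)^2))
    }, numeric(1))
    k <- cands[which.min(err)]
    params$k_auto <- TRUE
  }
  if (k < 1) stop("k must be >= 1")
  params$k <- k
  finish_result(data, llsi_estimates(data, k), "llsi", params)
}
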