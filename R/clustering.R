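# Gene clustering and cluster-stability indices. Distances between profiles
# use the normalized Euclidean distance d*, which skips coordinates missing
# in either profile and rescales by n/(n - m), m being the number of
# coordinates missing in one or both profiles. Agreement between a reference
# clustering (RC, computed on the complete matrix) and a generated clustering
# (GC, computed after masking + imputation) is scored by CPP, CPP_f and CAR.

#' Partition of genes into clusters
#'
#' @param labels integer cluster labels in `1..K`, named by gene identifier.
#' @param K cluster count; defaults to `max(labels)`.
#' @param source `"RC"` (reference clustering), `"GC"` (generated
#'   clustering) or `"true"` (generator labels).
#' @param algorithm name of the producing algorithm.
#' @return a `gene_partition` object.
#' @export
gene_partition <- function(labels, K = max(labels), source = "GC",
                           algorithm = "unknown") {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > K))
    stop("labels must be integers in 1..K")
  if (K < 1L) stop("K must be >= 1")
  structure(list(labels = labels, K = as.integer(K), source = source,
                 algorithm = algorithm),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("Gene partition (%s, %s): %d genes in %d clusters\n",
              x$source, x$algorithm, length(x$labels), x$K))
  invisible(x)
}

#' Normalized Euclidean distance between two profiles
#'
#' `d* = sqrt( n/(n - m) * sum over mutually observed coordinates of
#' (v_i - w_i)^2 )`, where `m` counts the coordinates missing in `v`, `w` or
#' both. Reduces to the plain Euclidean distance when both profiles are
#' complete.
#'
#' @param v,w numeric vectors of equal length; `NA` marks missing.
#' @return the distance, or `NA` if no coordinate is mutually observed.
#' @export
masked_euclidean_distance <- function(v, w) {
  if (length(v) != length(w)) stop("profiles must have equal length")
  both <- !is.na(v) & !is.na(w)
  nb <- sum(both)
  if (nb == 0L) return(NA_real_)
  sqrt(length(v) / nb * sum((v[both] - w[both])^2))
}

# All-pairs d* via three matrix products. Returns the distance matrix with
# NA where no coordinate is mutually observed, plus the mutual-observation
# counts.
masked_distance_core <- function(m) {
  W <- 1 * !is.na(m)
  X0 <- m; X0[is.na(m)] <- 0
  nobs <- tcrossprod(W)
  sq <- (X0^2) %*% t(W)
  d2 <- sq + t(sq) - 2 * tcrossprod(X0)
  d2 <- (ncol(m) / nobs) * d2   # Inf/NaN where nobs == 0
  d2[nobs == 0] <- NA_real_
  D <- sqrt(pmax(d2, 0))
  diag(D) <- 0
  list(D = D, nobs = nobs)
}

#' All-pairs profile distance matrix
#'
#' Computes d* between every pair of genes. Pairs with no mutually observed
#' coordinate are undefined; they are replaced by the largest finite distance
#' in the matrix, and their count is attached as attribute `n_undefined`.
#'
#' @param m expression matrix, possibly with missing values.
#' @return symmetric G x G matrix with zero diagonal.
#' @export
distance_matrix <- function(m) {
  validate_expression_matrix(m)
  D <- masked_distance_core(m)$D
  und <- is.na(D)
  if (any(und)) D[und] <- max(D[!und], 0)
  dimnames(D) <- list(rownames(m), rownames(m))
  attr(D, "n_undefined") <- sum(und) / 2
  D
}

#' Agglomerative hierarchical clustering cut to K clusters
#'
#' Thin wrapper over [stats::hclust()] covering the seven classical linkages.
#' Centroid and median linkage are run on squared distances (as their
#' Lance-Williams updates require); `ward` maps to the minimum-variance
#' criterion on Euclidean distances (`ward.D2`).
#'
#' @param d distance matrix (as from [distance_matrix()]) or `dist` object.
#' @param linkage one of `"single"`, `"complete"`, `"average"`,
#'   `"mcquitty"`, `"median"`, `"centroid"`, `"ward"`.
#' @param K number of clusters to cut the tree into.
#' @return a `gene_partition`.
#' @export
hierarchical_cluster <- function(d, linkage = c("ward", "single", "complete",
                                                "average", "mcquitty",
                                                "median", "centroid"),
                                 K) {
  linkage <- match.arg(linkage)
  dd <- stats::as.dist(d)
  if (K < 1L || K > attr(dd, "Size")) stop("K must be in 1..G")
  hc <- switch(linkage,
    median = ,
    centroid = stats::hclust(dd^2, method = linkage),
    ward = stats::hclust(dd, method = "ward.D2"),
    stats::hclust(dd, method = linkage))
  labels <- stats::cutree(hc, k = K)
  gene_partition(labels, K = K, algorithm = linkage)
}

#' K-means clustering of gene profiles
#'
#' Euclidean k-means with `restarts` random initializations; the solution
#' with the smallest within-cluster sum of squares is kept. Deterministic
#' given `seed`.
#'
#' @param m complete expression matrix.
#' @param K number of clusters.
#' @param restarts number of random starts.
#' @param seed integer seed.
#' @return a `gene_partition`.
#' @export
kmeans_cluster <- function(m, K, restarts = 10, seed = 1) {
  validate_expression_matrix(m, require_complete = TRUE)
  if (K < 1L || K > nrow(m)) stop("K must be in 1..G")
  km <- with_seed(seed,
    suppressWarnings(stats::kmeans(m, centers = K, nstart = restarts,
                                   iter.max = 100)))
  gene_partition(stats::setNames(km$cluster, rownames(m)), K = K,
                 algorithm = "kmeans")
}

check_same_universe <- function(rc, gc) {
  if (length(rc$labels) != length(gc$labels))
    stop("partitions cover different gene universes")
}

#' Conserved Pairs Proportion (CPP)
#'
#' For every reference cluster, the best-matching generated cluster is the
#' one sharing the most genes with it; CPP is 100 times the summed best-match
#' overlaps divided by the gene count.
#'
#' @param rc,gc `gene_partition` objects over the same genes.
#' @return percentage in (0, 100\].
#' @export
cpp <- function(rc, gc) {
  check_same_universe(rc, gc)
  tab <- table(factor(rc$labels, levels = seq_len(rc$K)),
               factor(gc$labels, levels = seq_len(gc$K)))
  100 * sum(apply(tab, 1L, max)) / length(rc$labels)
}

#' Relaxed Conserved Pairs Proportion (CPP_f)
#'
#' As [cpp()], but a gene of a reference cluster also counts when it falls in
#' one of the `f - 1` generated clusters whose centroids (mean profiles in
#' `m`) are nearest to the best-matching cluster's centroid.
#'
#' @param rc,gc `gene_partition` objects over the same genes.
#' @param m complete (post-imputation) expression matrix the GC was built on.
#' @param f neighbourhood size; `f = 1` reduces to [cpp()] exactly.
#' @return percentage in (0, 100\].
#' @export
cpp_f <- function(rc, gc, m, f = 5) {
  check_same_universe(rc, gc)
  if (f < 1L) stop("f must be >= 1")
  validate_expression_matrix(m, require_complete = TRUE)
  tab <- table(factor(rc$labels, levels = seq_len(rc$K)),
               factor(gc$labels, levels = seq_len(gc$K)))
  present <- sort(unique(gc$labels))
  cent <- rowsum(m, gc$labels) / as.vector(table(gc$labels))
  cd <- as.matrix(stats::dist(cent))   # centroid-centroid distances
  hits <- 0
  for (i in seq_len(rc$K)) {
    if (sum(tab[i, ]) == 0) next
    best <- present[which.max(tab[i, as.character(present)])]
    ord <- present[order(cd[as.character(best), as.character(present)],
                         present)]
    ord <- c(best, setdiff(ord, best))
    keep <- ord[seq_len(min(f, length(ord)))]
    hits <- hits + sum(tab[i, as.character(keep)])
  }
  100 * hits / length(rc$labels)
}

#' Clustering Agreement Ratio (CAR)
#'
#' Percentage of gene pairs concordant between the two partitions:
#' co-clustered in both or separated in both, out of `G(G-1)/2` pairs — the
#' Rand index scaled to 100. Computed from the contingency table in
#' `O(G + K^2)`.
#'
#' @param rc,gc `gene_partition` objects over the same genes.
#' @return percentage in \[0, 100\].
#' @export
car <- function(rc, gc) {
  check_same_universe(rc, gc)
  G <- length(rc$labels)
  if (G < 2L) stop("CAR needs at least 2 genes")
  tab <- table(rc$labels, gc$labels)
  npairs <- G * (G - 1) / 2
  a <- sum(choose(tab, 2))
  row_p <- sum(choose(rowSums(tab), 2))
  col_p <- sum(choose(colSums(tab), 2))
  100 * (npairs + 2 * a - row_p - col_p) / npairs
}

#' Mean within-cluster dispersion
#'
#' Mean over clusters of the average squared Euclidean distance of member
#' profiles to their cluster centroid; used to pick comparable cluster
#' counts across algorithms.
#'
#' @param p a `gene_partition`.
#' @param m complete expression matrix.
#' @return non-negative real.
#' @export
within_cluster_dispersion <- function(p, m) {
  validate_expression_matrix(m, require_complete = TRUE)
  if (length(p$labels) != nrow(m))
    stop("partition and matrix cover different gene sets")
  present <- sort(unique(p$labels))
  if (length(present) < p$K)
    warning("empty clusters excluded from dispersion")
  disp <- vapply(present, function(k) {
    sub <- m[p$labels == k, , drop = FALSE]
    cen <- colMeans(sub)
    mean(rowSums(sweep(sub, 2L, cen)^2))
  }, numeric(1))
  mean(disp)
}
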