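# Synthetic expression matrices with known cluster structure, emulating the
# shape of refined yeast/human log-ratio datasets: C co-expressed clusters,
# optional smooth (kinetic) temporal profiles, and a fraction of near-flat
# "null" genes that no filtering removed.

#' Generate a complete expression matrix with known clusters
#'
#' Non-kinetic mode draws C centroid vectors with independent
#' `N(0, sigma_between^2)` coordinates; kinetic mode uses smooth sinusoids
#' `a * sin(2*pi*t/n + phi) + b` with cluster-specific amplitude, phase and
#' offset drawn from seeded uniforms (`a` in `[0.5, 1.5] * sigma_between`,
#' `phi` in `[0, 2*pi)`, `b` in `[-1, 1] * sigma_between`), giving conditions
#' the serial correlation typical of time-course sets. Each non-flat gene is
#' its cluster centroid plus independent `N(0, sigma_within^2)` noise; flat
#' genes are pure noise around zero and carry the dedicated label `C + 1`.
#' Cluster membership is drawn uniformly; everything is deterministic given
#' `seed`. Defaults are shaped on a refined yeast subset of roughly 800
#' genes by 8 conditions; the kinetic mode is the default because
#' array-space estimators rely on inter-condition correlation, which
#' independent centroid coordinates cannot provide.
#'
#' @param G gene count.
#' @param n condition count.
#' @param C cluster count (flat genes form an extra class).
#' @param kinetic smooth temporal centroids instead of independent ones.
#' @param sigma_between spread of cluster centroids (log2 units).
#' @param sigma_within gene-level noise sd (log2 units).
#' @param flat_fraction fraction of near-flat null genes in \[0, 1).
#' @param seed integer seed.
#' @return list with `matrix` (complete expression matrix) and `labels`
#'   (a `gene_partition` with `source = "true"`; flat genes have label
#'   `C + 1`).
#' @export
generate_dataset <- function(G = 500, n = 8, C = 10, kinetic = TRUE,
                             sigma_between = 1.0, sigma_within = 0.25,
                             flat_fraction = 0.1, seed = 1) {
  if (G < C || C < 1) stop("need G >= C >= 1")
  if (n < 2) stop("need n >= 2")
  if (sigma_between < 0 || sigma_within < 0) stop("variances must be >= 0")
  if (flat_fraction < 0 || flat_fraction >= 1) stop("flat_fraction in [0, 1)")
  out <- with_seed(seed, {
    centroids <- if (kinetic) {
      a <- stats::runif(C, 0.5, 1.5) * sigma_between
      phi <- stats::runif(C, 0, 2 * pi)
      b <- stats::runif(C, -1, 1) * sigma_between
      t(vapply(seq_len(C),
               function(c) a[c] * sin(2 * pi * (seq_len(n) - 1) / n + phi[c]) + b[c],
               numeric(n)))
    } else {
      matrix(stats::rnorm(C * n, 0, sigma_between), C, n)
    }
    n_flat <- round_half_away(flat_fraction * G)
    labels <- rep(C + 1L, G)
    labels[seq_len(G - n_flat)] <- sample(rep_len(seq_len(C), G - n_flat))
    labels <- sample(labels)        # interleave flat genes
    vals <- matrix(stats::rnorm(G * n, 0, sigma_within), G, n)
    core <- labels <= C
    vals[core, ] <- vals[core, ] + centroids[labels[core], ]
    list(vals = vals, labels = labels, n_flat = n_flat)
  })
  m <- expression_matrix(out$vals,
                         gene_ids = sprintf("g%04d", seq_len(G)),
                         condition_ids = paste0("c", seq_len(n)))
  K <- C + as.integer(out$n_flat > 0)
  list(matrix = m,
       labels = gene_partition(stats::setNames(out$labels, rownames(m)),
                               K = max(K, max(out$labels)),
                               source = "true", algorithm = "generator"))
}
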