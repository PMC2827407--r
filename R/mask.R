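# Simulated missing-value masks. A masked dataset bundles a complete
# reference matrix, the set of erased positions and their held-out true
# values. tau is a percentage of eligible ENTRIES (all entries, or the
# extreme-value subset), and the masked count is round(tau/100 * |eligible|)
# with half rounded away from zero.

new_masked_dataset <- function(reference, mask, tau, scope, seed) {
  storage.mode(mask) <- "integer"
  colnames(mask) <- c("gene", "condition")
  structure(
    list(reference = reference, mask = mask,
         truth = reference[mask, drop = TRUE],
         tau = tau, scope = scope, seed = seed),
    class = "masked_dataset")
}

#' Simulate a uniform missing-value mask
#'
#' Erases `round(tau/100 * G * n)` distinct entries of a complete reference
#' matrix, drawn uniformly without replacement. No guard prevents a gene from
#' losing all its values at high `tau`; downstream imputers handle such rows
#' through their fallback chain.
#'
#' @param ref complete expression matrix.
#' @param tau missing rate as a percentage of all entries, in \[0, 50\].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a `masked_dataset`: list with elements `reference`, `mask` (two
#'   integer columns, gene and condition index), `truth` (erased values,
#'   parallel to the mask rows), `tau`, `scope` and `seed`.
#' @export
simulate_mask <- function(ref, tau, seed) {
  validate_expression_matrix(ref, require_complete = TRUE)
  if (tau < 0 || tau > 50) stop("tau must be in [0, 50]")
  G <- nrow(ref); n <- ncol(ref)
  size <- round_half_away(tau / 100 * G * n)
  mask <- if (size == 0L) empty_mask() else {
    lin <- sort(with_seed(seed, sample.int(G * n, size)))
    arrayInd(lin, c(G, n))
  }
  new_masked_dataset(ref, mask, tau, "all", seed)
}

#' Entries with the largest absolute values
#'
#' Returns the `round(fraction * G * n)` positions holding the largest
#' absolute log-ratios — the strongest up/down-regulation signals. Ties at
#' the cutoff are broken by (gene index, condition index) lexicographic
#' order.
#'
#' @param ref complete expression matrix.
#' @param fraction fraction of all entries, in (0, 1); default 0.01.
#' @return integer matrix with columns `gene`, `condition`.
#' @export
extreme_value_set <- function(ref, fraction = 0.01) {
  validate_expression_matrix(ref, require_complete = TRUE)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  G <- nrow(ref); n <- ncol(ref)
  size <- round_half_away(fraction * G * n)
  if (size < 1L) stop("fraction selects zero entries")
  pos <- arrayInd(seq_len(G * n), c(G, n))
  ord <- order(-abs(as.vector(ref)), pos[, 1L], pos[, 2L])
  out <- pos[ord[seq_len(size)], , drop = FALSE]
  storage.mode(out) <- "integer"
  colnames(out) <- c("gene", "condition")
  out
}

#' Simulate a mask restricted to extreme values
#'
#' Masks `round(tau/100 * |extreme set|)` entries drawn uniformly from the
#' extreme-value set, so e.g. `tau = 10` with the default 1% extreme set
#' erases 0.1% of all entries.
#'
#' @param ref complete expression matrix.
#' @param tau percentage of the extreme set to mask, in \[0, 100\].
#' @param fraction extreme-set fraction (see [extreme_value_set()]).
#' @param seed integer seed.
#' @return a `masked_dataset` with `scope = "extreme"`.
#' @export
simulate_extreme_mask <- function(ref, tau, fraction = 0.01, seed) {
  validate_expression_matrix(ref, require_complete = TRUE)
  if (tau < 0 || tau > 100) stop("tau must be in [0, 100]")
  ext <- extreme_value_set(ref, fraction)
  size <- round_half_away(tau / 100 * nrow(ext))
  mask <- if (size == 0L) empty_mask() else {
    sel <- sort(with_seed(seed, sample.int(nrow(ext), size)))
    ext[sel, , drop = FALSE]
  }
  new_masked_dataset(ref, mask, tau, "extreme", seed)
}

#' Matrix view of a masked dataset
#'
#' @param data a `masked_dataset`.
#' @return the reference matrix with `NA` at every masked position.
#' @export
masked_matrix <- function(data) {
  x <- data$reference
  if (nrow(data$mask)) x[data$mask] <- NA_real_
  x
}

#' Serialize a mask for audit
#'
#' Writes three tab-delimited columns: gene_id, condition_id, true_value.
#'
#' @param data a `masked_dataset`.
#' @param path output path.
#' @export
write_mask <- function(data, path) {
  df <- data.frame(
    gene_id = rownames(data$reference)[data$mask[, 1L]],
    condition_id = colnames(data$reference)[data$mask[, 2L]],
    true_value = data$truth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat(sprintf(
    "Masked dataset: %d x %d reference, %d masked entries (tau = %g%%, scope = %s)\n",
    nrow(x$reference), ncol(x$reference), nrow(x$mask), x$tau, x$scope))
  invisible(x)
}
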