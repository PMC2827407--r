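# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Derive a child seed (< 2^31) from a master seed and a counter, so any
# single (tau, replicate) cell is reproducible in isolation.
derive_seed <- function(master, counter) {
  master <- as.numeric(master) %% 2147483647
  counter <- as.numeric(counter) %% 2147483647
  as.integer((master * 69069 + counter * 1234567 + 987654321) %% 2147483647)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Moore-Penrose pseudoinverse via SVD.
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

# Linear index <-> (gene, condition) for a G x n grid, column-major.
linear_index <- function(mask, G) (mask[, 2L] - 1L) * G + mask[, 1L]

empty_mask <- function() {
  matrix(integer(0), nrow = 0, ncol = 2,
         dimnames = list(NULL, c("gene", "condition")))
}
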