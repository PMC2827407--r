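# Independent brute-force oracles and fixture builders. The oracles are
# deliberately written as plain loops over the definitions, separate from the
# package's vectorised implementations.

mat <- function(values, nrow, gene_ids = NULL, condition_ids = NULL) {
  m <- matrix(values, nrow = nrow, byrow = TRUE)
  expression_matrix(m, gene_ids, condition_ids)
}

random_matrix <- function(G, n, seed, na_frac = 0) {
  set.seed(seed)
  m <- matrix(rnorm(G * n), G, n)
  if (na_frac > 0) m[sample(G * n, round(na_frac * G * n))] <- NA
  expression_matrix(m)
}

# masked dataset with an explicit mask (gene, condition index pairs)
manual_mask <- function(ref, mask) {
  missbench:::new_masked_dataset(ref, mask, tau = NA_real_, scope = "all",
                                 seed = NA_integer_)
}

# d* by the definition, as a scalar loop
bf_dstar <- function(v, w) {
  n <- length(v); ss <- 0; nb <- 0
  for (i in seq_len(n)) {
    if (!is.na(v[i]) && !is.na(w[i])) {
      ss <- ss + (v[i] - w[i])^2
      nb <- nb + 1
    }
  }
  if (nb == 0) return(NA_real_)
  unname(sqrt(n / nb * ss))
}

# exhaustive kNN estimate for one masked entry, by the stated rule
bf_knn_entry <- function(X, g, j, k) {
  G <- nrow(X)
  cand <- c(); d <- c()
  for (h in seq_len(G)) {
    if (h == g || is.na(X[h, j])) next
    nb <- sum(!is.na(X[g, ]) & !is.na(X[h, ]))
    if (nb < 1) next
    cand <- c(cand, h)
    d <- c(d, bf_dstar(X[g, ], X[h, ]))
  }
  if (!length(cand)) return(NA_real_)
  ord <- order(d, cand)
  sel <- ord[seq_len(min(k, length(cand)))]
  w <- 1 / (d[sel] + 1e-9)
  sum(w * X[cand[sel], j]) / sum(w)
}

# Rand-type agreement by O(G^2) pair enumeration
bf_car <- function(l1, l2) {
  G <- length(l1); agree <- 0
  for (i in 1:(G - 1)) for (j in (i + 1):G) {
    same1 <- l1[i] == l1[j]
    same2 <- l2[i] == l2[j]
    if (same1 == same2) agree <- agree + 1
  }
  100 * agree / (G * (G - 1) / 2)
}

# paired one-sided sign test: does x tend to be smaller than y?
sign_test_less <- function(x, y) {
  wins <- sum(x < y); n <- sum(x != y)
  if (n == 0) return(1)
  stats::binom.test(wins, n, alternative = "greater")$p.value
}
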