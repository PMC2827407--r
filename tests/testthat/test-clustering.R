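# Masked distance, clustering wrappers, and the stability indices.

test_that("masked Euclidean distance matches the definition", {
  expect_identical(masked_euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(masked_euclidean_distance(c(1, 2, 3, 4), c(1, 2, 3, 0)), 4)
  # one MV: observed squared diffs sum to 16, n = 4, m = 1
  expect_equal(masked_euclidean_distance(c(1, 2, NA, 4), c(1, 2, 3, 0)),
               sqrt(4 / 3 * 16))
  expect_true(is.na(masked_euclidean_distance(c(NA, 1), c(2, NA))))
  set.seed(10)
  for (i in 1:25) {
    v <- rnorm(6); w <- rnorm(6)
    v[sample(6, 2)] <- NA; w[sample(6, 1)] <- NA
    expect_equal(masked_euclidean_distance(v, w), bf_dstar(v, w))
  }
})

test_that("distance matrix is symmetric, zero-diagonal, and exact", {
  m <- random_matrix(4, 3, seed = 11)
  D <- distance_matrix(m)
  expect_equal(unname(D), unname(as.matrix(dist(m))),
               ignore_attr = TRUE)                      # complete = Euclidean
  md <- random_matrix(15, 6, seed = 12, na_frac = 0.2)
  Dm <- distance_matrix(md)
  expect_equal(Dm, t(Dm), ignore_attr = TRUE)
  expect_identical(unname(diag(Dm)), rep(0, 15))
  for (i in 1:14) for (j in (i + 1):15)
    if (sum(!is.na(md[i, ]) & !is.na(md[j, ])) > 0)
      expect_equal(Dm[i, j], bf_dstar(md[i, ], md[j, ]))
  dup <- mat(c(1, 2, 3,
               1, 2, 3,
               5, 5, 5), nrow = 3)
  expect_equal(distance_matrix(dup)[1, 2], 0)
})

test_that("pairs with no shared coordinate get the max finite distance", {
  m <- mat(c(1, 2, NA, NA,
             NA, NA, 3, 4,
             1, 1, 1, 1), nrow = 3)
  D <- distance_matrix(m)
  expect_identical(attr(D, "n_undefined"), 1)
  finite_ds <- c(bf_dstar(m[1, ], m[3, ]), bf_dstar(m[2, ], m[3, ]))
  expect_equal(D[1, 2], max(finite_ds))
})

test_that("hierarchical clustering honours linkage and cut count", {
  # three collinear profiles at mutual distance ratios 1 : 2 : 3
  m <- mat(c(0, 0,
             1, 1,
             3, 3), nrow = 3)
  p <- hierarchical_cluster(distance_matrix(m), "single", 2)
  expect_identical(p$labels[1], p$labels[2])
  expect_false(p$labels[3] == p$labels[1])
  m2 <- random_matrix(8, 4, seed = 13)
  expect_identical(hierarchical_cluster(distance_matrix(m2), "average", 8)$K, 8L)
  expect_length(unique(hierarchical_cluster(distance_matrix(m2), "ward", 8)$labels), 8)
  expect_identical(unique(hierarchical_cluster(distance_matrix(m2), "complete", 1)$labels), 1L)
  for (lk in c("single", "complete", "average", "mcquitty", "median",
               "centroid", "ward"))
    expect_s3_class(hierarchical_cluster(distance_matrix(m2), lk, 3),
                    "gene_partition")
  expect_error(hierarchical_cluster(distance_matrix(m2), "warD", 3))
})

test_that("k-means separates well-separated blobs and is seeded", {
  set.seed(14)
  m <- expression_matrix(rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                               matrix(rnorm(40, 10, 0.1), 20, 2)))
  truth <- gene_partition(rep(1:2, each = 20), source = "true")
  p <- kmeans_cluster(m, 2, seed = 3)
  expect_equal(car(truth, p), 100)
  expect_identical(kmeans_cluster(m, 2, seed = 3)$labels, p$labels)
  p1 <- kmeans_cluster(m, 1, seed = 1)
  expect_identical(unique(p1$labels), 1L)
  expect_error(kmeans_cluster(m, 0, seed = 1), "K")
})

test_that("CPP counts best-match overlaps per reference cluster", {
  rc <- gene_partition(c(1, 1, 1, 2, 2), source = "RC")
  expect_equal(cpp(rc, rc), 100)
  gc <- gene_partition(c(1, 1, 2, 1, 2))
  expect_equal(cpp(rc, gc), 60)        # (2 + 1) / 5
  one <- gene_partition(rep(1, 5))
  expect_equal(cpp(rc, one), 100)      # every RC cluster wholly inside it
  expect_error(cpp(rc, gene_partition(c(1, 2))), "universe")
})

test_that("CPP_f relaxes CPP through centroid neighbourhoods", {
  set.seed(15)
  m <- expression_matrix(rbind(matrix(rnorm(30, 0), 10, 3),
                               matrix(rnorm(30, 4), 10, 3),
                               matrix(rnorm(30, 8), 10, 3)))
  rc <- gene_partition(rep(1:3, each = 10), source = "RC")
  gc <- gene_partition(c(rep(1, 8), 2, 2, rep(2, 8), 3, 3, rep(3, 10)))
  expect_equal(cpp_f(rc, gc, m, f = 1), cpp(rc, gc))
  expect_gte(cpp_f(rc, gc, m, f = 2), cpp(rc, gc))
  expect_equal(cpp_f(rc, gc, m, f = 3), 100)   # f >= K_GC saturates
  expect_error(cpp_f(rc, gc, m, f = 0), "f")
})

test_that("CAR equals pair enumeration and is label-symmetric", {
  rc <- gene_partition(c(1, 1, 2, 2), source = "RC")
  gc <- gene_partition(c(1, 2, 1, 2))
  expect_equal(car(rc, rc), 100)
  expect_equal(car(rc, gc), 100 * 2 / 6)   # only pairs (1,4) and (2,3) agree
  relab <- gene_partition(c(2, 1, 2, 1))
  expect_equal(car(rc, relab), car(rc, gc))
  set.seed(16)
  for (i in 1:5) {
    l1 <- sample(1:6, 100, replace = TRUE)
    l2 <- sample(1:4, 100, replace = TRUE)
    expect_equal(car(gene_partition(l1), gene_partition(l2)), bf_car(l1, l2))
  }
  expect_true(all(replicate(5, {
    l1 <- sample(1:3, 30, TRUE); l2 <- sample(1:3, 30, TRUE)
    v <- car(gene_partition(l1), gene_partition(l2)); v >= 0 && v <= 100
  })))
})

test_that("within-cluster dispersion follows centroid geometry", {
  m <- random_matrix(6, 3, seed = 17)
  singletons <- gene_partition(1:6)
  expect_equal(within_cluster_dispersion(singletons, m), 0)
  # one two-point cluster at distance d: mean squared distance to the
  # midpoint is d^2 / 4
  two <- mat(c(0, 0, 0,
               2, 0, 0), nrow = 2)
  d2 <- within_cluster_dispersion(gene_partition(c(1, 1)), two)
  expect_equal(d2, 4 / 4)
  # more clusters never hurt on a strongly clustered fixture
  gd <- generate_dataset(G = 60, n = 4, C = 3, sigma_within = 0.05,
                         flat_fraction = 0, seed = 18)
  disp <- vapply(1:6, function(K)
    within_cluster_dispersion(
      hierarchical_cluster(distance_matrix(gd$matrix), "ward", K),
      gd$matrix), numeric(1))
  expect_true(all(diff(disp) <= 1e-12))
})
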