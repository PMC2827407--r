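# Reading, writing, filtering and subsampling of expression matrices.

write_lines <- function(lines) {
  p <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("plain files parse with missing tokens and preserved order", {
  p <- write_lines(c("GID\tc1\tc2",
                     "gA\t1.5\tNA",
                     "gB\t-0.25\t2",
                     "gC\t0\t3.5"))
  m <- read_matrix(p)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("gA", "gB", "gC"))
  expect_identical(sum(is.na(m)), 1L)
  expect_true(is.na(m["gA", "c2"]))
  expect_equal(m["gB", ], c(c1 = -0.25, c2 = 2))
})

test_that("pcl dialect skips GWEIGHT/NAME columns and EWEIGHT rows", {
  plain <- write_lines(c("GID\tc1\tc2", "gA\t1\t2", "gB\t3\tnan"))
  pcl <- write_lines(c("GID\tNAME\tGWEIGHT\tc1\tc2",
                       "EWEIGHT\t\t\t1\t1",
                       "gA\tgene A\t1\t1\t2",
                       "gB\tgene B\t1\t3\tnan"))
  expect_identical(read_matrix(pcl, "pcl"), read_matrix(plain))
})

test_that("malformed input is rejected with a useful message", {
  ragged <- write_lines(c("GID\tc1\tc2\tc3",
                          "gA\t1\t2\t3",
                          "gB\t1\t2\t3\t4"))
  expect_error(read_matrix(ragged), "line 3")
  dup <- write_lines(c("GID\tc1\tc2", "gA\t1\t2", "gA\t3\t4"))
  expect_error(read_matrix(dup), "duplicate gene ID")
  allna <- write_lines(c("GID\tc1\tc2", "gA\tNA\tNA", "gB\t\tNaN"))
  expect_error(read_matrix(allna), "no observed values")
})

test_that("write/read round-trips values and missing flags in both dialects", {
  m <- random_matrix(10, 8, seed = 42, na_frac = 0.1)
  for (dialect in c("plain", "pcl")) {
    p <- withr::local_tempfile(fileext = ".txt")
    write_matrix(m, p, dialect)
    m2 <- read_matrix(p, dialect)
    expect_identical(is.na(m2), is.na(m))
    expect_equal(m2, m, tolerance = 1e-12)
  }
  bad <- m
  rownames(bad)[1] <- ""
  p <- withr::local_tempfile()
  expect_error(write_matrix(bad, p), "non-empty")
})

test_that("reference-matrix filter drops conditions first, then genes", {
  # gene 2 carries the only MV: single-gene drop
  m <- random_matrix(5, 4, seed = 1)
  m[2, 3] <- NA
  ref <- build_reference_matrix(m)
  expect_identical(dim(ref), c(4L, 4L))
  expect_identical(rownames(ref), rownames(m)[-2])
  expect_identical(ref, m[-2, ])

  # condition 3 has 4 MVs (> threshold 3) and genes 1, 2 have one MV
  # elsewhere: the condition goes first, then the two genes
  m2 <- random_matrix(6, 5, seed = 2)
  m2[3:6, 3] <- NA
  m2[1, 1] <- NA
  m2[2, 5] <- NA
  ref2 <- build_reference_matrix(m2, max_mv_per_condition = 3)
  expect_identical(dim(ref2), c(4L, 4L))
  expect_identical(rownames(ref2), rownames(m2)[3:6])
  expect_identical(colnames(ref2), colnames(m2)[-3])

  # complete input is the identity, and the filter is idempotent
  ok <- random_matrix(4, 4, seed = 3)
  expect_identical(build_reference_matrix(ok), ok)
  expect_identical(build_reference_matrix(ref2, 3), ref2)
  # threshold 0 drops every MV-carrying condition outright
  expect_identical(dim(build_reference_matrix(m2, 0)), c(6L, 2L))
  spread <- random_matrix(4, 4, seed = 4)
  diag(spread) <- NA
  expect_error(build_reference_matrix(spread, max_mv_per_condition = 0),
               "fewer than 2 conditions")
  expect_error(build_reference_matrix(spread), "fewer than 2 genes")
})

test_that("gene subsampling is seeded, order-preserving and sized by rounding", {
  m <- random_matrix(70, 4, seed = 7)
  s <- subsample_genes(m, 1 / 7, seed = 5)
  expect_identical(nrow(s), 10L)
  expect_identical(s, m[rownames(s), ])          # values untouched
  expect_false(is.unsorted(match(rownames(s), rownames(m))))
  expect_identical(subsample_genes(m, 1 / 7, seed = 5), s)
  expect_false(identical(subsample_genes(m, 1 / 7, seed = 6), s))
  expect_identical(subsample_genes(m, 1, seed = 1), m)
  expect_error(subsample_genes(m, 0, seed = 1), "fraction")
  expect_error(subsample_genes(m, 1.2, seed = 1), "fraction")
})
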