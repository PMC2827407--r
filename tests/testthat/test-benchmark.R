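# Benchmark orchestration: design combinatorics, shared masks, determinism,
# incremental output and summaries.

small_config <- function(output_dir = NULL, master_seed = 5) {
  benchmark_config(
    datasets = list(syn = list(G = 30, n = 6, C = 3, seed = 1)),
    methods = c("row_mean", "knn"),
    tau_grid = c(5, 10, 20),
    replicates = 2,
    clustering = NULL,
    master_seed = master_seed,
    output_dir = output_dir)
}

test_that("record count enumerates the design exactly", {
  recs <- run_benchmark(small_config())
  expect_identical(nrow(recs), 12L)    # 1 dataset x 2 methods x 3 tau x 2 reps
  expect_true(all(recs$error == ""))
  expect_true(all(is.finite(recs$rmse)))
})

test_that("the default tau grid has 100 levels", {
  cfg <- benchmark_config(datasets = list(a = list(G = 20, n = 4, C = 2)),
                          methods = "row_mean")
  expect_length(cfg$tau_grid, 100)
  expect_equal(range(cfg$tau_grid), c(0.5, 50))
})

test_that("every method sees the identical mask within a design cell", {
  recs <- run_benchmark(small_config())
  for (key in unique(paste(recs$tau, recs$replicate))) {
    cell <- recs[paste(recs$tau, recs$replicate) == key, ]
    expect_identical(unique(cell$seed), cell$seed[1])
    expect_identical(unique(cell$n_entries), cell$n_entries[1])
  }
})

test_that("reruns with the same master seed reproduce the rmse column", {
  r1 <- run_benchmark(small_config())
  r2 <- run_benchmark(small_config())
  expect_identical(r1$rmse, r2$rmse)
  r3 <- run_benchmark(small_config(master_seed = 6))
  expect_false(identical(r1$rmse, r3$rmse))
})

test_that("records stream to disk and resume skips completed cells", {
  dir <- withr::local_tempdir()
  r1 <- run_benchmark(small_config(output_dir = dir))
  on_disk <- read.delim(file.path(dir, "records.tsv"))
  expect_identical(nrow(on_disk), 12L)
  expect_equal(on_disk$rmse, r1$rmse)
  r2 <- run_benchmark(small_config(output_dir = dir), resume = TRUE)
  expect_null(r2)                        # nothing left to do
})

test_that("stability indices are recorded per clustering algorithm", {
  cfg <- benchmark_config(
    datasets = list(syn = list(G = 40, n = 6, C = 4, seed = 2)),
    methods = "knn", tau_grid = 10, replicates = 2,
    clustering = list(list(algorithm = "ward", K = 5),
                      list(algorithm = "kmeans", K = 5)),
    master_seed = 7)
  recs <- run_benchmark(cfg)
  for (col in c("cpp_ward5", "cppf_ward5", "car_ward5",
                "cpp_kmeans5", "cppf_kmeans5", "car_kmeans5")) {
    expect_true(col %in% names(recs))
    expect_true(all(recs[[col]] >= 0 & recs[[col]] <= 100))
  }
  expect_true(all(recs$cppf_ward5 >= recs$cpp_ward5))
})

test_that("summaries match an independent spreadsheet-style aggregation", {
  recs <- expand.grid(method = c("A", "B"), dataset = c("d1", "d2"),
                      tau = c(5, 10), replicate = 1:3,
                      stringsAsFactors = FALSE)
  set.seed(99)
  recs$rmse <- round(runif(nrow(recs), 0.05, 0.5), 3)
  recs$rmse[recs$method == "A"] <- recs$rmse[recs$method == "A"] / 10
  s <- summarize_benchmark(recs)
  for (m in c("A", "B")) for (ds in c("d1", "d2"))
    expect_equal(s$mean_rmse[m, ds],
                 mean(recs$rmse[recs$method == m & recs$dataset == ds]))
  expect_equal(s$mean_rmse["A", "mean"],
               mean(s$mean_rmse["A", c("d1", "d2")]))
  expect_equal(unname(s$wins$pooled["A", "B"]), 100)
  expect_equal(unname(s$wins$d1["B", "A"]), 0)
})

test_that("configuration validation rejects bad designs", {
  ds <- list(a = list(G = 20, n = 4, C = 2))
  expect_error(benchmark_config(ds, methods = character(0)), "non-empty")
  expect_error(benchmark_config(ds, "knn", tau_grid = c(10, 60)), "tau_grid")
  expect_error(benchmark_config(ds, "knn", replicates = 0), "replicates")
  expect_error(benchmark_config(ds, "knn", scopes = "half"), "scope")
  expect_error(benchmark_config(list(list(G = 20, n = 4, C = 2)), "knn"),
               "named")
})
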