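# Benchmark driver: sweeps datasets x methods x tau grid x replicates x
# scopes, sharing one mask per design cell across all methods (pairwise
# comparisons require paired simulations), and aggregates results.

#' Assemble and validate a benchmark configuration
#'
#' @param datasets named list; each element is either a complete expression
#'   matrix or a list of [generate_dataset()] arguments (a synthetic spec).
#' @param methods character vector of method names, or a named list mapping
#'   method names to hyperparameter lists.
#' @param tau_grid missing rates (percent) in (0, 50\]; default the classical
#'   0.5-50 by 0.5 sweep.
#' @param replicates simulations per (dataset, tau, scope) cell.
#' @param scopes subset of `c("all", "extreme")`.
#' @param extreme_fraction extreme-value set fraction.
#' @param clustering list of `list(algorithm=, K=)` entries; algorithms are
#'   the seven hierarchical linkages or `"kmeans"`. `NULL` disables
#'   stability scoring.
#' @param master_seed seed from which every cell's seed is derived.
#' @param output_dir if non-`NULL`, records are appended incrementally to
#'   `records.tsv` in this directory and a rerun with `resume = TRUE` skips
#'   completed cells.
#' @return a `benchmark_config` list.
#' @export
benchmark_config <- function(datasets, methods, tau_grid = seq(0.5, 50, 0.5),
                             replicates = 10, scopes = "all",
                             extreme_fraction = 0.01,
                             clustering = list(list(algorithm = "ward", K = 10)),
                             master_seed = 1, output_dir = NULL) {
  if (!length(methods)) stop("methods must be non-empty")
  if (is.character(methods))
    methods <- stats::setNames(rep(list(list()), length(methods)), methods)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("datasets must be named")
  if (any(tau_grid <= 0 | tau_grid > 50)) stop("tau_grid values must be in (0, 50]")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!all(scopes %in% c("all", "extreme"))) stop("unknown scope")
  structure(list(datasets = datasets, methods = methods, tau_grid = tau_grid,
                 replicates = replicates, scopes = scopes,
                 extreme_fraction = extreme_fraction, clustering = clustering,
                 master_seed = master_seed, output_dir = output_dir),
            class = "benchmark_config")
}

#' Number of simulations per method implied by a configuration
#'
#' One simulation is one (dataset, scope, tau, replicate) cell; each method
#' imputes every simulation once.
#'
#' @param config a `benchmark_config`.
#' @return integer count.
#' @export
design_size <- function(config) {
  length(config$datasets) * length(config$scopes) *
    length(config$tau_grid) * config$replicates
}

resolve_dataset <- function(d) {
  if (is.matrix(d)) {
    validate_expression_matrix(d, require_complete = TRUE)
    d
  } else do.call(generate_dataset, d)$matrix
}

#' Run the full mask-impute-score benchmark
#'
#' For each dataset the reference clusterings (RC) are computed once on the
#' complete matrix; then for each (scope, tau, replicate) cell one mask is
#' drawn (its seed derived from `master_seed` and the cell counter) and
#' every method imputes that same mask. RMSE, the predicted-true
#' correlation, fallback counts and — per configured clustering algorithm —
#' CPP, CPP_f and CAR of the post-imputation clustering are recorded. A
#' failing cell is recorded with `NA` scores and an error message, not
#' fatal.
#'
#' @param config a `benchmark_config`.
#' @param resume skip cells already present in `output_dir/records.tsv`.
#' @return data frame of benchmark records (one row per dataset x method x
#'   scope x tau x replicate), invisibly also written to `output_dir`.
#' @export
run_benchmark <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  out_path <- NULL
  done_keys <- character(0)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out_path <- file.path(config$output_dir, "records.tsv")
    if (resume && file.exists(out_path)) {
      prev <- utils::read.delim(out_path)
      done_keys <- do.call(paste, c(prev[c("dataset", "method", "scope",
                                           "tau", "replicate")], sep = "\r"))
    } else if (file.exists(out_path)) file.remove(out_path)
  }
  clus <- config$clustering
  records <- list()
  cell <- 0L
  for (ds_name in names(config$datasets)) {
    ref <- resolve_dataset(config$datasets[[ds_name]])
    rc <- lapply(clus, function(cl) {
      if (cl$algorithm == "kmeans")
        kmeans_cluster(ref, cl$K, seed = derive_seed(config$master_seed, 0L))
      else hierarchical_cluster(distance_matrix(ref), cl$algorithm, cl$K)
    })
    for (scope in config$scopes) for (tau in config$tau_grid)
      for (rep_i in seq_len(config$replicates)) {
        cell <- cell + 1L
        cell_seed <- derive_seed(config$master_seed, cell)
        data <- if (scope == "all") simulate_mask(ref, tau, cell_seed)
          else simulate_extreme_mask(ref, tau, config$extreme_fraction,
                                     cell_seed)
        for (mi in seq_along(config$methods)) {
          method <- names(config$methods)[mi]
          key <- paste(ds_name, method, scope, tau, rep_i, sep = "\r")
          if (key %in% done_keys) next
          rec <- data.frame(dataset = ds_name, method = method,
                            scope = scope, tau = tau, replicate = rep_i,
                            seed = cell_seed, n_entries = nrow(data$mask),
                            rmse = NA_real_, r = NA_real_,
                            fallback_n = NA_integer_, error = "")
          for (cl in clus)
            for (pre in c("cpp_", "cppf_", "car_"))
              rec[[paste0(pre, cl$algorithm, cl$K)]] <- NA_real_
          res <- tryCatch({
            args <- config$methods[[mi]]
            if (method %in% c("llsi", "lsi_combined", "lsi_adaptive") &&
                is.null(args$seed))
              args$seed <- derive_seed(cell_seed, mi)
            do.call(impute, c(list(data = data, method = method), args))
          }, error = function(e) e)
          if (inherits(res, "error")) {
            rec$error <- conditionMessage(res)
          } else {
            rec$rmse <- if (nrow(data$mask)) rmse(res, data) else NA_real_
            rec$r <- if (nrow(data$mask) >= 3)
              predicted_true_correlation(res, data) else NA_real_
            rec$fallback_n <- sum(res$params$fallback[-1L])
            for (ci in seq_along(clus)) {
              cl <- clus[[ci]]
              gc <- tryCatch({
                if (cl$algorithm == "kmeans")
                  kmeans_cluster(res$completed, cl$K,
                                 seed = derive_seed(config$master_seed, 0L))
                else hierarchical_cluster(distance_matrix(res$completed),
                                          cl$algorithm, cl$K)
              }, error = function(e) NULL)
              tag <- paste0(cl$algorithm, cl$K)
              rec[[paste0("cpp_", tag)]] <-
                if (is.null(gc)) NA_real_ else cpp(rc[[ci]], gc)
              rec[[paste0("cppf_", tag)]] <-
                if (is.null(gc)) NA_real_ else cpp_f(rc[[ci]], gc, res$completed)
              rec[[paste0("car_", tag)]] <-
                if (is.null(gc)) NA_real_ else car(rc[[ci]], gc)
            }
          }
          records[[length(records) + 1L]] <- rec
          if (!is.null(out_path))
            suppressWarnings(utils::write.table(
              rec, out_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !file.exists(out_path), append = TRUE))
        }
      }
  }
  do.call(rbind, records)
}

#' Summarize benchmark records
#'
#' @param records data frame from [run_benchmark()].
#' @return list with `mean_rmse` (methods x datasets grid with row/column
#'   means), `wins` (pooled pairwise win matrix, plus one per dataset) and
#'   `stability` (mean CPP/CPP_f/CAR per method and clustering algorithm).
#' @export
summarize_benchmark <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("no records to summarize")
  mr <- tapply(records$rmse, records[c("method", "dataset")], mean,
               na.rm = TRUE)
  mean_rmse <- cbind(mr, mean = rowMeans(mr, na.rm = TRUE))
  mean_rmse <- rbind(mean_rmse, mean = colMeans(mean_rmse, na.rm = TRUE))
  wins <- list(pooled = pairwise_win_matrix(records))
  for (ds in unique(records$dataset))
    wins[[ds]] <- pairwise_win_matrix(records[records$dataset == ds, ])
  stab_cols <- grep("^(cpp|cppf|car)_", names(records), value = TRUE)
  stability <- if (length(stab_cols)) {
    agg <- stats::aggregate(records[stab_cols],
                            by = records[c("method", "dataset")],
                            FUN = mean, na.rm = TRUE)
    agg
  } else NULL
  list(mean_rmse = mean_rmse, wins = wins, stability = stability)
}
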