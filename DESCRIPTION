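Package: missbench
Title: Benchmarking Missing-Value Imputation and Gene-Cluster Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates missing values at controlled rates in complete
    gene-expression matrices, restores them with ten classical imputation
    methods (row mean, k-nearest neighbours, sequential kNN, local least
    squares, and least-squares and expectation-maximisation estimators in
    gene and array space), scores the reconstructions by root mean square
    error, and quantifies how imputation error propagates to the stability
    of gene clusters obtained by hierarchical and k-means clustering via
    conserved-pair proportions and a Rand-type agreement ratio. Includes a
    synthetic expression-data generator with known cluster structure and a
    benchmark driver sweeping missing rates, replicates and methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
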