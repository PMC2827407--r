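---
title: "Benchmarking missing-value imputation and its effect on gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missing-value imputation and its effect on gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missbench)
```

## The problem

Microarray (and other expression) experiments routinely lose measurements:
corrupted spots are filtered during image analysis and become missing values
(MVs) in the genes x conditions log-ratio matrix. Downstream analyses —
above all the clustering of genes into putative co-regulated groups — either
discard incomplete genes or work on imputed values, and the choice of
imputation method changes both the numerical error of the restored values
and the stability of the resulting clusters.

`missbench` quantifies both effects with a simulate-mask / impute / score
pipeline:

1. start from a **complete reference matrix** (genes with MVs removed);
2. erase a controlled fraction τ of entries at random, remembering the true
   values;
3. restore them with each imputation method;
4. score the restoration by **RMSE** against the held-out truth;
5. re-cluster the completed matrix and score cluster stability against the
   reference clustering with **CPP**, **CPP_f** and **CAR**.

Because each simulation cell shares one mask across all methods, per-cell
comparisons are paired and pairwise win rates are meaningful.

## Distances, indices and their definitions

Profiles with missing coordinates are compared with the normalized
Euclidean distance

d\*(v, w) = sqrt( n/(n−m) · Σ over mutually observed i of (v_i − w_i)² ),

where n is the profile length and m the number of coordinates missing in
either profile; d\* reduces to the plain Euclidean distance for complete
profiles. A pair with no shared observed coordinate has no defined distance;
`distance_matrix()` substitutes the largest finite distance in the matrix
and counts the substitutions, which keeps the matrix usable at extreme τ
without inventing similarity.

Agreement between the reference clustering RC (computed on the complete
matrix) and a generated clustering GC (after masking + imputation) is
scored three ways:

* **CPP** — for each RC cluster, find the GC cluster sharing the most genes
  with it; CPP is the summed best-match overlap as a percentage of all
  genes. This operationalizes the "maximal proportion of genes belonging to
  two clusters" as a per-reference-cluster best-match sum; normalization is
  by the gene count G.
* **CPP_f** — as CPP, but a gene also counts when it lands in one of the
  f−1 GC clusters whose centroids (mean profiles) are closest to the
  best-matching cluster's centroid; `f = 1` reduces exactly to CPP, and
  f ≥ K saturates at 100. Centroid proximity in expression space is our
  concretization of "the f closer groups".
* **CAR** — the percentage of gene pairs treated concordantly (co-clustered
  in both partitions, or separated in both) out of G(G−1)/2; this is the
  Rand index scaled to 100, computed from the K×K′ contingency table in
  O(G + K²) and cross-checked in the tests against O(G²) pair enumeration.

Hierarchical clustering goes through `stats::hclust()` (the seven classical
linkages; centroid and median linkage on squared distances, Ward as the
minimum-variance `ward.D2` criterion) and k-means through `stats::kmeans()`
with seeded multi-starts. `within_cluster_dispersion()` reports the mean
within-cluster squared distance to the centroid, the quantity used to pick
comparable cluster counts when contrasting k-means with hierarchical
solutions.

## The simulated-MV model

τ is a percentage of **eligible entries** — all G·n entries for the
uniform scope, or the extreme-value subset (the `fraction` = 1% of entries
with the largest |log-ratio|) for the extreme scope, so τ = 10% of the 1%
extreme set erases 0.1% of the matrix. The masked count is
round(τ/100 · |eligible|) with halves rounded away from zero (unbiased over
a regular τ grid). Entries are drawn uniformly without replacement; nothing
prevents a gene from losing every value at high τ — robustness is the
imputers' job, via the fallback chain below. A master seed spawns one
derived seed per (τ, replicate) cell, so any single cell is reproducible in
isolation.

## The ten replacement methods

All methods share one contract: unmasked entries are returned bit-for-bit,
every masked entry receives a finite estimate, and wherever a method's own
estimate is undefined the estimate falls through the chain *gene observed
mean → condition observed mean → global observed mean → 0*, with counts
reported in `params$fallback`.

| method | idea | main tuning |
|---|---|---|
| `row_mean` | mean of the gene's observed values | — |
| `knn` | weighted mean of the k nearest donors (d\*, weights 1/(d\*+1e−9)) | k (default 15) |
| `sknn` | sequential kNN: least-missing genes first, imputed genes join the donor pool | k |
| `llsi` | least squares on the k nearest complete genes, solved by pseudoinverse | k or `"auto"` |
| `lsi_gene` | per-entry regression on the K most-correlated genes, weights (r²/(1−r²+1e−6))² | K (default 10) |
| `lsi_array` | MVN conditional expectation from complete-gene moments | ridge 1e−8 |
| `lsi_combined` | p·gene + (1−p)·array, global p | p or `"auto"` |
| `lsi_adaptive` | per-entry p, binned by the entry's best neighbour correlation r_max | bins (10) |
| `em_gene` | EM in the (K+1)-gene neighbourhood space | K, ridge 1e−6 |
| `em_array` | EM for an MVN over conditions, genes as observations | tol 1e−6, max 300 iter |

Design notes, where the original method descriptions leave room:

* **k for kNN/SkNN.** The default k = 15 sits in the range over which the
  classical kNN-imputation literature reports stable accuracy;
  `select_k_opt()` implements the usual alternative, minimizing the error
  on a secondarily masked 5% of the observed entries over a candidate grid
  (ties to the smallest k).
* **Secondary masking** is also how `llsi` picks k ∈ {5, 10, 15, 20}, how
  `lsi_combined` picks its global mixing weight p over {0, 0.01, …, 1},
  and how `lsi_adaptive` picks one p per r_max bin (bins with fewer than 20
  secondary entries inherit the global p). The secondary mask is drawn from
  the observed entries only and removed afterwards.
* **EM specifics.** `em_array` initializes MVs by row means, computes exact
  per-pattern conditional expectations and conditional covariances in the
  E-step, and uses the MLE update with conditional-covariance correction in
  the M-step. The observed-data log-likelihood, evaluated with the
  parameters entering each E-step, is recorded and is non-decreasing (a
  1e−8 ridge is applied only when solving Σ_OO, so monotonicity holds to
  numerical precision; the tests assert it on every fixture). Convergence
  is a relative change in (μ, Σ) below `tol`; non-convergence is a warning
  plus `converged = FALSE`, never an error. `em_gene` reuses the same
  machinery per gene in the space of the gene and its K most-correlated
  neighbours; with n conditions as the only observations that system is
  usually rank-deficient, so a 1e−6 ridge enters the covariance update
  itself.
* **Correlation guards.** Pearson correlations are only trusted on ≥ 3
  mutually observed coordinates, and candidates that are constant over the
  shared coordinates (undefined r) are disqualified.
* **BPCA** is a registry name reserved for an external plugin and raises a
  not-implemented error: it is a cited algorithm we do not define.

## The synthetic generator

`generate_dataset()` emulates the *shape* of refined expression sets: G
genes (default 500) by n conditions (8), C co-expression clusters (10),
cluster spread `sigma_between` (1.0 log2 units), per-gene noise
`sigma_within` (0.25), and a `flat_fraction` (10%) of near-zero "null"
genes that survive because no profile filtering is applied — exactly the
genes that later inflate apparent cluster stability for mean-reverting
imputers.

Two centroid models are available. The non-kinetic model draws each
centroid coordinate independently; the kinetic model draws smooth
sinusoids a·sin(2πt/n + φ) + b per cluster. The kinetic model is the
default: independent centroid coordinates give the conditions no mutual
correlation in expectation, and without inter-condition correlation the
array-space estimators have nothing to work with; the sinusoid family
spans a rank-3 linear subspace ({1, sin, cos}) and provides the serial
correlation that time-course sets exhibit.

What the generator deliberately does **not** reproduce: empirical
log-ratio value distributions, spot-level or dye-bias noise, correlated
corruption patterns, and — importantly — the loose, continuum-like cluster
structure of real data. The default design places ~50 close profiles in
every cluster, a much denser donor pool than a real microarray provides,
so neighbour-based methods (kNN/SkNN) perform unusually well here relative
to their published behaviour on real datasets; conclusions about the
*relative* merits of neighbour vs array-space methods on real data should
not be read off this generator. The package's tests therefore assert the
robust comparisons (array-space EM versus row mean; degradation of cluster
stability with τ) and check the methods' internal correctness against
closed forms and brute-force oracles rather than chasing a particular
published ranking.

## Numerical and design choices

* RMSE is unnormalized, on the log2-ratio scale; a normalized variant
  (divide by sd of the truths) sits behind `normalized = TRUE`.
* Win rates give ties half a win to each side, so the matrix is exactly
  antisymmetric.
* Masked counts use round-half-away-from-zero; R's banker's rounding would
  bias a regular τ grid.
* Merge ties inside `stats::hclust` follow R's own deterministic order;
  dendrograms are reproducible, though not forced to the smallest-index
  merge convention.
* The condition-drop threshold of `build_reference_matrix()` is an absolute
  MV count (disabled by default) because any specific cutoff is
  dataset-specific; gene order is never re-sorted by any operation, which
  keeps seeded subsampling reproducible.
* `kmeans_cluster()` defaults to 10 restarts; recovery tests use 30 so that
  local optima do not confound a recoverability check.

## Problem sizes used by the tests

The shipped tests and the acceptance script run entirely on generated
data: unit fixtures of 3–60 genes for closed-form and oracle checks,
150-gene datasets for recovery properties (30 seeds), and the default
500 × 8 generator for the ranking and stability checks (10–30 replicates,
τ ∈ {0.5, 10, 20}). The full classical sweep — τ from 0.5 to 50 by 0.5,
100 replicates, several datasets — is what `benchmark_config()` defaults
describe; at that scale `run_benchmark()` writes records incrementally and
can resume, since such sweeps run for hours.

## Known limitations

* `em_array` requires n ≤ 64 conditions (dense covariance over conditions).
* CPP's original normalization (by gene count, per-reference-cluster best
  match) and CPP_f's neighbourhood rule are our operationalizations of
  verbal descriptions; alternative normalizations exist in the literature.
* The generator's tight clusters favour neighbour methods (above); there is
  no missing-not-at-random mechanism and no spatially correlated corruption.
* Method combination/ensembling and BPCA are out of scope.
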