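---
title: "Recovering gene-gene correlations from dropout-heavy scRNA-seq by graph k-partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering gene-gene correlations from dropout-heavy scRNA-seq by graph k-partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partcor)
```

## The problem

A single-cell RNA-seq matrix is mostly zeros. Many of those zeros are
*dropout* — transcripts that were present in the cell but were not captured
or amplified — rather than true absence of expression. For gene-pair
analysis this is fatal: if each gene's measurement survives in only ~10% of
cells, the two genes are jointly observed in ~1% of cells, and the Pearson
correlation between them is attenuated almost to zero regardless of how
strongly they co-vary biologically.

partcor implements a simple, imputation-free answer. Cells that sit close
together on a 2D transcriptomic embedding (typically tSNE) have similar
expression states. If we partition such cells into k small clusters and
average each gene's expression within a cluster — zeros included — the
dropout noise, which is independent across cells, averages out, while the
biological differences *between* clusters remain. Gene-pair correlation is
then estimated across the k cluster means instead of across single cells.

The zero-abundance argument is quantitative: if an entry is zero with
probability p independently per cell, the merged value over m cells is zero
with probability p^m. At p = 0.95 this falls from 95% (single cell) to 90%
(2 cells), 8% (50 cells) and under 1% (100 cells):

```{r zerocurve}
expected_merged_zero_fraction(0.95, c(1, 2, 10, 50, 100))
```

`run_merge_simulation()` reproduces this curve by Monte Carlo on an
explicit Bernoulli mask; the closed form `p^m` is its analytic reference.

## The partitioning procedure

1. **Scale** the embedding so the largest absolute coordinate equals a
   target half-range (`scale_embedding()`). All distances below are in
   these scaled units.
2. **Graph**: connect every pair of cells at Euclidean distance at most a
   cutoff (default 3; `build_cell_graph()`). Because modularity treats edge
   weight as affinity, the default weight is the inverted distance
   `cutoff - d + 1e-6`; `raw-distance` and `unweighted` modes exist for
   fidelity experiments (raw distances invert the intended affinity
   ordering, which is why they are not the default).
3. **Over-segment**: Louvain community detection, escalating the
   resolution geometrically (x1.5, at most 20 rounds) until the community
   count N exceeds the requested k (`louvain_oversegment()`).
4. **Merge to exactly k**: repeatedly merge the pair of clusters with the
   smallest centroid distance among pairs that share at least one graph
   edge; centroids are recomputed from member cells after every merge.
   When no adjacent pair remains while N > k (disconnected components),
   the globally closest pair is merged instead. Ties break on the
   lexicographically smallest label pair. Final labels are 1..k by
   descending size (`merge_to_k()`, `partition()`).

`partition_series()` walks a *single* merge path and snapshots it at each
requested k, so the resulting clusterings are nested by construction —
every cluster at a smaller k is a union of clusters at any larger k. That
nesting is what the evolution tree (`build_tree()`, `layout_ladder()`,
`layout_circle()`) visualizes.

### Choosing the scale: a density rule

The cutoff is meaningful only relative to the typical spacing between
neighbouring cells. If the expected nearest-neighbour distance exceeds the
cutoff, the graph fragments into isolated cells, which then occupy cluster
slots as permanent singletons and starve the connected part of the
embedding of clusters. A workable rule of thumb: after scaling, the local
cell density should give a nearest-neighbour spacing clearly below the
cutoff, i.e. half-range roughly `0.5 * cutoff * sqrt(n_cells)` or less.
The `"auto"` setting (200 up to 8000 cells, 400 beyond) matches tSNE maps
at the cell counts where this method is usually applied; for the ~2000-cell
simulated datasets used in this package's tests we set the half-range to
25–60 for the same reason.

### Small clusters

Clusters holding fewer than ~10 cells defeat the purpose of averaging: at
95% zeros a 9-cell mean still has a ~63% chance of being exactly zero, and
such means are nearly as noisy as single cells. `filter_small_clusters()`
either absorbs undersized clusters into their nearest-centroid neighbour
(`merge`) or marks their cells unassigned (`drop`). We recommend
`min_cells = 10` before any downstream correlation or classification; the
high-leverage noise points that tiny clusters contribute can otherwise
dominate a correlation computed over only k observations.

## Correlation testing

`cluster_profile()` computes the k x genes matrix of within-cluster means
(zeros included); a size-weighted average of the cluster means reproduces
the global gene mean exactly, which is asserted in the tests.
`correlate_pairs()` tests each requested gene pair across the k cluster
means (or across raw cells, for the baseline): Pearson r with a two-sided
p-value from the Gaussian linear-model slope test, which is algebraically
the classical correlation t-test `t = r * sqrt((n-2)/(1-r^2))` on n-2
degrees of freedom — stated explicitly so nobody expects a count-model
likelihood behind the "glm" phrasing. Spearman coefficients come from rank
transformation followed by the same machinery. Benjamini–Hochberg
adjustment runs over all non-degenerate tests (constant genes are excluded
from the family — no valid statistic exists for them), and pairs are
declared significant at q < 0.05 by default.

### Unit weighting and null calibration

By default every cluster counts as one observation, matching the plain
per-cluster averaging approach. When cluster sizes are very uneven this has
a quantifiable side effect: the variance of a cluster mean scales with
1/size, and because *both* genes of a pair share the same size pattern,
independent genes acquire a common heteroscedasticity that inflates the
null tail of r (we measured a 2–3x excess of null p-values below 0.005 in
simulations with cluster sizes spanning 10–100 cells). For FDR-sensitive
analyses `correlate_pairs(..., weight_by_size = TRUE)` computes the
size-weighted Pearson coefficient, which restores calibration and slightly
improves power; the default stays unweighted for fidelity to the plain
method.

`compare_cluster_vs_cell()` runs the same pairs at cell level and cluster
level side by side, and `stability_scan()` tracks the top pairs (ranked at
a reference k, default 100) across a series of cluster numbers to identify
the range over which r and p are stable.

## Classification

`auc_vs_k_scan()` demonstrates the same denoising on a supervised task:
cluster-mean profiles inherit a binary label by majority vote
(`label_clusters()`, ties to the lexicographically first label) and a
ridge-regularized logistic classifier is cross-validated on the units.
Folds are stratified by class; the most variable genes (default 500) are
selected inside each training split to avoid leakage; the AUC is computed
from pooled out-of-fold scores (a per-fold average is also reported, but
pooled is the headline number). The raw single-cell baseline runs the same
classifier under the same seed, and with k equal to the number of cells
the cluster pipeline reduces to the baseline exactly — singleton clusters
preserve cell order, so the fold assignment, feature selection and fitted
models coincide.

The classifier itself is deliberately generic (the method's claim is about
the features, not the classifier); it sits behind a narrow train/score
contract and can be swapped.

## The synthetic-data generator

`simulate_dataset()` produces the test bed: a latent log-normal expression
matrix, an entry-wise independent Bernoulli dropout mask at a configurable
rate (default 0.95), Gaussian-blob embeddings (one blob per cell type), and
optional type-specific marker genes.

One design choice deserves emphasis. If latent gene-gene correlation were
i.i.d. across cells, within-cluster averaging would *not* help: averaging
i.i.d. pairs shrinks covariance and variances by the same factor, leaving
the correlation of the means equal to the correlation of the cells. The
method works on real data because cells near each other in the embedding
share expression state — the embedding is computed *from* expression. The
generator therefore routes the leading factor of each correlated gene
component through a per-cell state that varies linearly (in a random
direction) across the embedding, with the remaining factors as per-cell
noise. The marginal per-cell log-scale correlation of each pair still
equals the requested rho (the factor loadings come from the
eigendecomposition of the requested correlation matrix, which is also
where a non-positive-semi-definite request is detected and rejected with
the offending pairs named). On the observed scale the no-dropout
correlation of a pair follows the log-normal identity
`(e^rho - 1)/(e - 1)`, which the tests use as a closed-form oracle.

What the generator does *not* emulate: UMI count noise and library-size
variation (the mask is the only noise source besides the latent model),
batch effects, and the irregular geometry of real tSNE maps (Gaussian
blobs have thin tails that produce a few isolated stragglers — see the
density rule above). Passing tests therefore show that the machinery is
correct under the stated generative model, not that the method is
validated on real tissue.

An expression-dependent dropout mode (zero probability decreasing
logistically in latent log-expression) is available but off by default,
matching the independence assumption of the zero-merge analysis.

## Numerical choices and edge cases

* Distances are thresholded in the *scaled* coordinate system; the cutoff
  default of 3 assumes that convention.
* Edge weights add an epsilon (1e-6) so zero-distance duplicate cells get
  positive weight.
* Merging recomputes centroids from exact coordinate sums, and the
  nearest-partner caches are updated incrementally; the result is asserted
  against a rescan-everything greedy oracle in the tests.
* `k = n_cells` bypasses graph construction entirely and returns singleton
  clusters in cell order, making the identity limits exact to the last bit.
* Constant vectors yield `status = "degenerate"` rather than NaN; missing
  gene ids yield `status = "missing"`; both are excluded from the BH family.
* Perfect correlation (|r| = 1) reports p = 0 rather than evaluating the
  t formula at a pole.
* All randomness (generator, Louvain, fold assignment) flows from explicit
  seeds, and seeded runs restore the caller's RNG state.

## Problem sizes used in the tests

The automated checks run the full chain at desk scale, chosen once: the
zero-merge simulation at 2,300 genes x 2,000 cells with 100 repetitions
per merge size; correlation recovery at 2,000 cells, latent rho 0.8,
dropout 0.9, k = 50, over 50 seeded replicates; detection at 1,000 genes
(50 true pairs at rho 0.7, 450 null pairs), k = 100, 20 replicates;
classification at 2,000 cells, two types, ten markers, 10-fold CV, 10
replicates. The full-scale configuration (23,000 genes x 20,000 cells,
1,000 repetitions) is supported by the same code paths.

## Known limitations

* The embedding is an input, not a product: the package does not compute
  tSNE/UMAP, and the quality of the partition inherits the quality of the
  embedding.
* Greedy centroid merging concentrates mass when the graph contains many
  permanently isolated cells (see the density rule); inspect
  `cells_per_cluster_summary()` and filter small clusters before relying
  on downstream estimates.
* Cluster-level tests treat clusters as independent observations; spatial
  overlap between adjacent clusters makes them mildly dependent, which the
  t reference ignores.
* Only pair lists are tested (no all-vs-all correlation matrices), and
  only 2D embeddings are supported.
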