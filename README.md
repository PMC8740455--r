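# partcor

Graph-based k-partitioning of single cells to recover gene–gene
correlations from dropout-heavy scRNA-seq data.

## Why

Single-cell RNA-seq matrices are ~90–95% zeros, largely technical
"dropout". Because each gene survives measurement in only a small fraction
of cells, the per-cell Pearson correlation between two genuinely
co-expressed genes is attenuated toward zero. partcor avoids imputation
entirely: it partitions transcriptomically similar cells into k
mini-clusters on a graph built from a 2D embedding (e.g. tSNE), averages
expression — zeros included — within each cluster, and estimates gene-pair
correlations across the k cluster means, where per-cell dropout noise has
averaged out. The zero-abundance argument is exact under independent
dropout at rate *p*: a merged value over *m* cells is zero with probability
*p^m* (0.95 → 0.0769 at *m* = 50).

The procedure, for cells with a 2D embedding:

1. scale the embedding to a target half-range (`scale_embedding`),
2. connect cells within a distance cutoff (default 3 scaled units) into a
   weighted graph (`build_cell_graph`),
3. over-segment with Louvain into N > k communities, escalating the
   resolution until N exceeds k (`louvain_oversegment`),
4. greedily merge the adjacent cluster pair with the smallest centroid
   distance until exactly k clusters remain (`merge_to_k`, `partition`),
5. average each gene within each cluster (`cluster_profile`) and test gene
   pairs across cluster means with BH FDR control (`correlate_pairs`),
   where the p-value comes from the Gaussian linear-model slope test,
   algebraically `t = r·sqrt((n−2)/(1−r²))` on n−2 df.

Also included: nested partition series along one merge path
(`partition_series`), cluster evolution trees with ladder/circle layouts
(`build_tree`), cluster-size diagnostics and small-cluster filtering,
cross-validated cell-type classification on cluster profiles
(`auc_vs_k_scan`), a synthetic-data generator with known ground truth
(`simulate_dataset`), the merged-cell zero-fraction simulation
(`run_merge_simulation`), Matrix-Market/TSV readers and writers, a YAML
pipeline runner (`run_pipeline`), and a command-line wrapper in
`inst/cli/partcor`.

## Worked example

Simulate 500 genes × 2000 cells at 90% dropout with two latent gene pairs
(log-scale rho 0.8 and 0.6), partition into 50 clusters, and compare
cluster-level against single-cell correlation:

```r
library(partcor)

cfg <- sim_config(n_genes = 500, n_cells = 2000, zero_prob = 0.9,
  latent_pairs = data.frame(gene_a = 1:2, gene_b = 3:4, rho = c(0.8, 0.6)),
  seed = 42)
sim <- simulate_dataset(cfg)
sim
#> Synthetic scRNA-seq dataset: 500 genes x 2000 cells (90.0% zeros observed)
#>   1 cell type(s); dropout mode: independent; seed 42

cl <- partition(sim$embedding, k = 50, scale = 25, seed = 42)
cl <- filter_small_clusters(cl, min_cells = 10, mode = "merge")
summary(cl)
#> Cells per cluster: expected 60.61; observed min 20, median 57, max 118
#>   clusters below 10 cells: 0

genes <- rownames(sim$expression)
pairs <- data.frame(gene_a = genes[c(1, 2, 10)], gene_b = genes[c(3, 4, 20)])
cmp <- compare_cluster_vs_cell(sim$expression, sim$embedding, pairs,
                               k = 50, scale = 25, seed = 42, min_cells = 10)
cmp[, c("gene_a", "gene_b", "r_cell", "r_cluster", "q_cluster")]
#>   gene_a gene_b  r_cell r_cluster q_cluster
#> 1   g001   g003 0.06852      0.87   1.9e-10
#> 2   g002   g004 0.00036      0.64   1.0e-04
#> 3   g010   g020 0.02540      0.19   2.9e-01
```

The two truly correlated pairs are invisible at cell level (r = 0.069 and
0.0004) but come out strongly at cluster level (r = 0.87 and 0.64, BH
q ≪ 0.05), while the null pair stays non-significant. The `scale = 25`
choice follows the density rule discussed in the methods vignette: the
cutoff must exceed the typical nearest-neighbour spacing of the embedding.

The same objects feed the other tools: `partition_series()` +
`build_tree()` trace how clusters split as k grows, `stability_scan()`
tracks the top pairs across cluster numbers, and `auc_vs_k_scan()`
cross-validates cell-type prediction from cluster profiles against the
raw single-cell baseline.

## Documentation

The methods vignette (`vignettes/cluster-correlation.Rmd`) describes the
model and its assumptions, the tunable parameters and their defaults, what
the synthetic generator does and does not emulate, numerical edge cases,
and known limitations. Every exported function carries roxygen
documentation.
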