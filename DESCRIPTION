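Package: partcor
Title: Graph-Based k-Partitioning of Single Cells for Gene-Gene Correlation Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers gene-gene correlations in zero-inflated ("dropout")
    single-cell RNA-seq data by partitioning transcriptomically similar cells
    into k mini-clusters on a graph built from a 2D embedding, averaging
    expression (zeros included) within each cluster, and testing gene-pair
    correlations at the cluster level with Benjamini-Hochberg FDR control.
    Includes a distance-threshold graph builder with Louvain over-segmentation
    and greedy centroid merging to exactly k clusters, cluster-size
    diagnostics, evolution tracing of clusters across a series of k values
    (ladder and circle layouts), cluster-profile-based cell-type
    classification with cross-validated AUC, a synthetic-data generator with
    known ground truth, and a merged-cell zero-fraction simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    glmnet,
    pROC,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
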