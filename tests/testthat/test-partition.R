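# Greedy merge-to-k, the composed partitioner, series nesting, diagnostics
# and small-cluster filtering.

make_graph <- function(emb, cutoff) suppressMessages(build_cell_graph(emb, cutoff))

test_that("merging three singletons picks the closest centroid pair", {
  emb <- cbind(x = c(0, 1, 10), y = c(0, 0, 0))
  rownames(emb) <- c("a", "b", "c")
  g <- make_graph(emb, cutoff = 15)       # all pairs adjacent
  cl0 <- as_clustering(setNames(1:3, rownames(emb)), emb)
  out <- merge_to_k(cl0, g, 2)
  expect_equal(out$k, 2L)
  expect_identical(partition_sets(out), list(c(1L, 2L), 3L))
  ## sizes sorted descending, centroids are member means
  expect_equal(out$sizes, c(2L, 1L))
  expect_equal(unname(out$centroids[, "x"]), c(0.5, 10))
})

test_that("merge with N == k returns the input partition", {
  be <- blob_embedding(20, rbind(c(0, 0), c(30, 0)), sd = 1, seed = 3)
  g <- make_graph(be$emb, cutoff = 5)
  cl <- louvain_oversegment(g, k = 2, seed = 1)
  out <- merge_to_k(cl, g, cl$k)
  expect_identical(partition_sets(out), partition_sets(cl))
  expect_error(merge_to_k(cl, g, cl$k + 1), "1..N")
  expect_error(merge_to_k(cl, g, 0), "1..N")
})

test_that("merge sequence equals the brute-force greedy oracle", {
  set.seed(42)
  n <- 200
  emb <- cbind(x = runif(n, 0, 40), y = runif(n, 0, 40))
  rownames(emb) <- sprintf("c%03d", seq_len(n))
  g <- make_graph(emb, cutoff = 4)
  start <- louvain_oversegment(g, k = 30, seed = 7)
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  edges <- data.frame(i = el[, 1], j = el[, 2])
  for (k in c(25, 12, 5)) {
    got <- merge_to_k(start, g, k)
    want <- oracle_greedy_merge(start$assignment, emb, edges, k)
    expect_identical(partition_sets(got), partition_sets(want))
  }
})

test_that("global fallback merges disconnected clusters when needed", {
  ## three isolated cells: no adjacency at cutoff 1, fallback on centroids
  emb <- cbind(x = c(0, 5, 11), y = c(0, 0, 0))
  g <- suppressWarnings(make_graph(emb, cutoff = 1))
  cl0 <- as_clustering(setNames(1:3, rownames(g$coords)), emb)
  out <- merge_to_k(cl0, g, 2)
  expect_identical(partition_sets(out), list(c(1L, 2L), 3L))
})

test_that("partition returns exactly k non-empty clusters with all cells", {
  be <- blob_embedding(500, rbind(c(0, 0), c(25, 0), c(0, 25), c(25, 25)),
                       sd = 2, seed = 5)
  for (k in c(1L, 10L, 100L)) {
    cl <- suppressMessages(partition(be$emb, k, scale = 60, seed = 2))
    expect_equal(cl$k, k)
    expect_false(anyNA(cl$assignment))
    expect_equal(length(cl$sizes), k)
    expect_true(all(cl$sizes >= 1L))
    expect_equal(sum(cl$sizes), nrow(be$emb))
  }
})

test_that("k = 1 and k = n_cells are exact boundary partitions", {
  emb <- blob_embedding(30, rbind(c(0, 0)), sd = 2, seed = 6)$emb
  one <- suppressMessages(partition(emb, 1, scale = 30, seed = 1))
  expect_equal(one$k, 1L)
  expect_equal(one$sizes, 30L)
  all_k <- partition(emb, 30)
  expect_equal(all_k$k, 30L)
  expect_equal(all_k$sizes, rep(1L, 30))
  ## singleton clusters preserve cell order
  expect_equal(unname(all_k$assignment), 1:30)
  expect_error(partition(emb, 31), "1..n_cells")
})

test_that("well-separated blobs are never mixed within a cluster", {
  be <- blob_embedding(150, rbind(c(0, 0), c(40, 0), c(20, 35)), sd = 1.5,
                       seed = 9)
  cl <- suppressMessages(partition(be$emb, 4, scale = 60, seed = 3))
  purity <- tapply(be$labels, cl$assignment, function(v) length(unique(v)))
  expect_true(all(purity == 1))
  ## with k = number of blobs the blob structure is recovered exactly
  cl3 <- suppressMessages(partition(be$emb, 3, scale = 60, seed = 3))
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(mclust::adjustedRandIndex(cl3$assignment, be$labels), 1)
  } else {
    expect_true(all(tapply(be$labels, cl3$assignment,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("identical inputs and seed give identical partitions", {
  be <- blob_embedding(200, rbind(c(0, 0), c(20, 0)), sd = 2, seed = 12)
  p1 <- suppressMessages(partition(be$emb, 15, scale = 50, seed = 4))
  p2 <- suppressMessages(partition(be$emb, 15, scale = 50, seed = 4))
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$centroids, p2$centroids)
})

test_that("series snapshots are nested along one merge path", {
  be <- blob_embedding(300, rbind(c(0, 0), c(25, 0)), sd = 2, seed = 15)
  ks <- c(10L, 20L, 40L)
  ser <- suppressMessages(partition_series(be$emb, ks, scale = 50, seed = 6))
  expect_equal(ser$ks, ks)
  for (i in seq_along(ks)[-1]) {
    small <- ser[[ks[i - 1]]]$assignment
    large <- ser[[ks[i]]]$assignment
    ## every larger-k cluster lies inside exactly one smaller-k cluster
    spread <- tapply(small[names(large)], large, function(v) length(unique(v)))
    expect_true(all(spread == 1))
  }
  ## a one-element series equals a direct partition under the same seed
  ser50 <- suppressMessages(partition_series(be$emb, 25, scale = 50, seed = 6))
  p50 <- suppressMessages(partition(be$emb, 25, scale = 50, seed = 6))
  expect_identical(ser50[[25]]$assignment, p50$assignment)
})

test_that("centroids equal the arithmetic mean of member coordinates", {
  be <- blob_embedding(120, rbind(c(0, 0), c(15, 0)), sd = 2, seed = 18)
  cl <- suppressMessages(partition(be$emb, 8, scale = 40, seed = 2))
  semb <- scale_embedding(be$emb, 40)
  for (c in seq_len(cl$k)) {
    members <- names(cl$assignment)[cl$assignment == c]
    expect_equal(unname(cl$centroids[c, ]),
                 unname(colMeans(semb[members, , drop = FALSE])),
                 tolerance = 1e-10)
  }
})

test_that("cluster-size summary reports the n/k expectation", {
  cl <- as_clustering(setNames(rep(1:3, c(90, 9, 1)), sprintf("c%d", 1:100)))
  s <- cells_per_cluster_summary(cl, min_cells = 10)
  expect_equal(s$expected, 100 / 3)
  expect_equal(s$n_below, 2L)
  expect_equal(s$table$size, c(90L, 9L, 1L))
  ## uniform case
  cl2 <- as_clustering(setNames(rep(1:10, each = 100), sprintf("c%d", 1:1000)))
  s2 <- cells_per_cluster_summary(cl2)
  expect_equal(s2$expected, 100)
  expect_equal(s2$median, 100)
})

test_that("partition sizes stay within a factor of 3 of n/k on one blob", {
  emb <- blob_embedding(1000, rbind(c(0, 0)), sd = 2, seed = 20)$emb
  cl <- suppressMessages(partition(emb, 100, scale = 25, seed = 5))
  s <- cells_per_cluster_summary(cl)
  expect_gt(s$median, s$expected / 3)
  expect_lt(s$median, s$expected * 3)
})

test_that("small-cluster filtering merges or drops as requested", {
  coords <- rbind(matrix(rnorm(10, sd = 0.2), 5, 2),
                  matrix(rnorm(100, sd = 0.2) + 8, 50, 2))
  rownames(coords) <- sprintf("c%d", 1:55)
  cl <- as_clustering(setNames(rep(c(1, 2), c(5, 50)), rownames(coords)), coords)
  merged <- filter_small_clusters(cl, min_cells = 10, mode = "merge")
  expect_equal(merged$k, 1L)
  expect_equal(merged$sizes, 55L)
  dropped <- filter_small_clusters(cl, min_cells = 10, mode = "drop")
  expect_equal(dropped$k, 1L)
  expect_equal(dropped$sizes, 50L)
  expect_equal(sum(is.na(dropped$assignment)), 5L)
  ## untouched when everything is large enough
  ok <- filter_small_clusters(cl, min_cells = 5, mode = "merge")
  expect_identical(ok$assignment, cl$assignment)
  expect_error(filter_small_clusters(cl, min_cells = 0), "min_cells")
})

test_that("merge-mode filtering absorbs into the nearest centroid", {
  coords <- rbind(matrix(c(0, 0, 0.1, 0.1, 0.2, 0.2), 3, 2, byrow = TRUE),
                  matrix(rnorm(60, sd = 0.3) + 5, 30, 2),
                  matrix(rnorm(60, sd = 0.3) + 50, 30, 2))
  rownames(coords) <- sprintf("c%d", seq_len(nrow(coords)))
  cl <- as_clustering(setNames(rep(1:3, c(3, 30, 30)), rownames(coords)), coords)
  out <- filter_small_clusters(cl, min_cells = 5, mode = "merge")
  expect_equal(out$k, 2L)
  ## the 3-cell cluster joins the blob at 5, not the one at 50
  expect_equal(sort(out$sizes), c(30L, 33L))
  joined <- out$assignment[rownames(coords)[1]]
  expect_equal(unname(out$assignment[4]), unname(joined))
})
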