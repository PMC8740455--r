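# Cluster profiles, the correlation test machinery, BH adjustment, and the
# cluster-vs-cell comparison.

test_that("cluster profile averages include zeros and conserve means", {
  expr <- tiny_expr(c(2, 5, 0, 1, 0, 0, 4, 2), 2, 4)  # 2 genes x 4 cells
  cl <- as_clustering(setNames(c(1, 1, 2, 2), colnames(expr)))
  prof <- cluster_profile(expr, cl)
  expect_equal(dim(prof), c(2L, 2L))
  expect_equal(unname(prof[, "g1"]), c(1, 2))          # (2+0)/2, (0+4)/2
  expect_equal(unname(prof[, "g2"]), c(3, 1))          # (5+1)/2, (0+2)/2
  ## size-weighted cluster means reproduce the global gene means
  sizes <- attr(prof, "sizes")
  global <- rowMeans(expr)
  back <- colSums(prof * sizes) / sum(sizes)
  expect_equal(unname(back), unname(global), tolerance = 1e-10)
  ## cluster means bounded by per-gene min/max over cells
  expect_true(all(t(prof) >= apply(expr, 1, min) - 1e-12))
  expect_true(all(t(prof) <= apply(expr, 1, max) + 1e-12))
})

test_that("singleton clusters give back the expression matrix", {
  set.seed(8)
  expr <- tiny_expr(rpois(60, 2), 6, 10)
  cl <- as_clustering(setNames(1:10, colnames(expr)))
  prof <- cluster_profile(expr, cl)
  expect_equal(unclass(prof), t(expr), ignore_attr = TRUE)
  ## all-zero gene stays all-zero
  expr0 <- expr; expr0[1, ] <- 0
  prof0 <- cluster_profile(expr0, as_clustering(setNames(rep(1:2, 5),
                                                         colnames(expr))))
  expect_equal(unname(prof0[, "g1"]), c(0, 0))
})

test_that("sparse and dense expression give the same profile", {
  set.seed(9)
  expr <- tiny_expr(rbinom(80, 1, 0.3) * runif(80), 8, 10)
  cl <- as_clustering(setNames(rep(1:2, each = 5), colnames(expr)))
  p1 <- cluster_profile(expr, cl)
  p2 <- cluster_profile(Matrix::Matrix(expr, sparse = TRUE), cl)
  expect_equal(unclass(p1), unclass(p2))
})

test_that("pair test equals the linear-model slope test", {
  expect_equal(correlate_pair(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(correlate_pair(1:10, 2 * (1:10) + 1)$p, 0)
  expect_equal(correlate_pair(rep(2, 5), rnorm(5))$status, "degenerate")
  expect_error(correlate_pair(1:4, 1:5), "equal length")
  expect_error(correlate_pair(1:2, 1:2), "at least 3")
  set.seed(10)
  for (i in 1:50) {
    x <- rnorm(20); y <- rnorm(20)
    got <- correlate_pair(x, y)
    fit <- summary(lm(y ~ x))
    expect_equal(got$p, fit$coefficients["x", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(got$r, cor(x, y), tolerance = 1e-12)
    gs <- correlate_pair(x, y, method = "spearman")
    expect_equal(gs$r, cor(x, y, method = "spearman"), tolerance = 1e-12)
    rfit <- summary(lm(rank(y) ~ rank(x)))
    expect_equal(gs$p, rfit$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("BH q-values match an independent step-up implementation", {
  set.seed(12)
  expr <- tiny_expr(rnorm(30 * 40, 5), 30, 40)
  pairs <- data.frame(gene_a = sprintf("g%d", 1:15),
                      gene_b = sprintf("g%d", 16:30))
  res <- correlate_pairs(expr, pairs)
  expect_equal(res$q, oracle_bh(res$p))
  expect_false(is.unsorted(res$p))
  ## m = 1: q equals p
  one <- correlate_pairs(expr, pairs[1, ])
  expect_equal(one$q, one$p)
  ## big random p-vector sanity on the oracle itself
  p <- runif(5000)
  expect_equal(oracle_bh(p), p.adjust(p, "BH"))
})

test_that("degenerate and missing pairs are excluded from the BH family", {
  expr <- tiny_expr(rnorm(40, 5), 4, 10)
  expr[1, ] <- 7                                      # constant gene
  pairs <- data.frame(gene_a = c("g1", "g2", "gX"),
                      gene_b = c("g2", "g3", "g4"))
  expect_message(res <- correlate_pairs(expr, pairs), "skipped")
  expect_equal(res$status[match(c("g1", "gX"), res$gene_a)],
               c("degenerate", "missing"))
  ok <- res$status == "ok"
  expect_equal(sum(ok), 1L)
  expect_equal(res$q[ok], res$p[ok])                  # family size 1
  expect_true(all(is.na(res$q[!ok])))
  expect_error(correlate_pairs(expr, pairs[0, ]), "empty")
  expect_error(correlate_pairs(expr, data.frame(a = "gX", b = "gY")),
               "none of the pair genes")
})

test_that("weighted correlation matches cov.wt and collapses to unweighted", {
  set.seed(31)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  w <- runif(30, 1, 10)
  got <- correlate_pair(x, y, weights = w)
  want <- stats::cov.wt(cbind(x, y), wt = w / sum(w), cor = TRUE,
                        method = "ML")$cor[1, 2]
  expect_equal(got$r, want, tolerance = 1e-12)
  ## equal weights reproduce the unweighted test exactly
  eq <- correlate_pair(x, y, weights = rep(2, 30))
  un <- correlate_pair(x, y)
  expect_equal(eq$r, un$r, tolerance = 1e-12)
  expect_equal(eq$p, un$p, tolerance = 1e-12)
  expect_error(correlate_pair(x, y, weights = w[-1]), "weights")
  ## the flag needs cluster sizes, so plain matrices are refused
  expr <- tiny_expr(rnorm(40, 5), 4, 10)
  expect_error(correlate_pairs(expr, data.frame(a = "g1", b = "g2"),
                               weight_by_size = TRUE), "cluster_profile")
  ## on a profile, weighting runs and flows into q-values
  cl <- as_clustering(setNames(rep(1:5, each = 2), colnames(expr)))
  prof <- cluster_profile(expr, cl)
  res <- correlate_pairs(prof, data.frame(a = "g1", b = "g2"),
                         weight_by_size = TRUE)
  expect_equal(res$status, "ok")
  expect_equal(res$q, res$p)
})

test_that("with k = n_cells the comparison collapses to the cell level", {
  sim <- simulate_dataset(sim_config(12, 150, zero_prob = 0.8,
    latent_pairs = data.frame(gene_a = 1, gene_b = 2, rho = 0.7), seed = 44))
  pairs <- data.frame(gene_a = c("g01", "g03"), gene_b = c("g02", "g04"))
  cmp <- compare_cluster_vs_cell(sim$expression, sim$embedding, pairs,
                                 k = 150, seed = 1)
  expect_equal(cmp$r_cell, cmp$r_cluster, tolerance = 1e-14)
  expect_equal(cmp$p_cell, cmp$p_cluster, tolerance = 1e-14)
  expect_true(all(cmp$agreement))
})

test_that("cluster averaging recovers a latent pair that dropout hides", {
  sim <- simulate_dataset(sim_config(6, 1500, zero_prob = 0.9,
    latent_pairs = data.frame(gene_a = 1, gene_b = 2, rho = 0.8), seed = 55))
  cmp <- suppressMessages(compare_cluster_vs_cell(
    sim$expression, sim$embedding,
    data.frame(gene_a = "g1", gene_b = "g2"), k = 50, scale = 25, seed = 2,
    min_cells = 10))
  expect_gt(abs(cmp$r_cluster), abs(cmp$r_cell))
  expect_gt(cmp$r_cluster, 0.4)
})

test_that("stability scan tracks the reference top pairs across k", {
  sim <- simulate_dataset(sim_config(10, 400, zero_prob = 0.8,
    latent_pairs = data.frame(gene_a = c(1, 3), gene_b = c(2, 4),
                              rho = c(0.8, 0.6)), seed = 66))
  genes <- rownames(sim$expression)
  pairs <- data.frame(gene_a = genes[c(1, 3, 5, 7)],
                      gene_b = genes[c(2, 4, 6, 8)])
  ks <- c(15L, 30L, 400L)
  sc <- suppressMessages(stability_scan(sim$expression, sim$embedding, pairs,
                                        ks = ks, reference_k = 30, top_n = 3,
                                        scale = 50, seed = 3))
  expect_equal(unique(sc$k), ks)
  expect_equal(nrow(sc), 9L)
  ## the k = n column equals the plain single-cell result
  cell <- correlate_pairs(sim$expression, pairs)
  at_n <- sc[sc$k == 400L, ]
  m <- match(paste(at_n$gene_a, at_n$gene_b), paste(cell$gene_a, cell$gene_b))
  expect_equal(at_n$r, cell$r[m], tolerance = 1e-12)
  expect_equal(at_n$p, cell$p[m], tolerance = 1e-12)
  ## reference-only scan returns the reference ranking
  ref <- suppressMessages(stability_scan(sim$expression, sim$embedding, pairs,
                                         ks = 30L, reference_k = 30, top_n = 3,
                                         scale = 50, seed = 3))
  expect_equal(nrow(ref), 3L)
  expect_false(is.unsorted(ref$p))
  expect_error(stability_scan(sim$expression, sim$embedding, pairs,
                              ks = c(10L, 20L), reference_k = 30),
               "reference_k")
})

test_that("null pairs produce uniform cell-level p-values", {
  set.seed(13)
  expr <- tiny_expr(rnorm(100 * 200, 5), 100, 200)
  pairs <- data.frame(gene_a = sprintf("g%d", 1:50),
                      gene_b = sprintf("g%d", 51:100))
  res <- correlate_pairs(expr, pairs)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(sum(res$significant), 5)
})
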