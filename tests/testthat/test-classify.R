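# Majority-vote labels, cross-validated AUC, and the k scan.

test_that("majority vote labels clusters and flags ties", {
  cells <- sprintf("c%02d", 1:20)
  cl <- as_clustering(setNames(rep(1:2, each = 10), cells))
  pure <- setNames(rep(c("A", "B"), each = 10), cells)
  lab <- label_clusters(cl, pure)
  expect_equal(lab$label, c("A", "B"))
  expect_equal(lab$majority_fraction, c(1, 1))
  mixed <- setNames(c(rep("A", 6), rep("B", 4), rep("A", 5), rep("B", 5)), cells)
  lab2 <- label_clusters(cl, mixed)
  expect_equal(lab2$label, c("A", "A"))            # tie -> lexicographic
  expect_equal(lab2$majority_fraction, c(0.6, 0.5))
})

test_that("perfectly separated profiles score AUC 1", {
  set.seed(21)
  n <- 40
  feat <- matrix(rnorm(n * 20), n, 20)
  feat[1:20, 1:5] <- feat[1:20, 1:5] + 10          # disjoint ranges
  rownames(feat) <- sprintf("u%d", 1:n)
  colnames(feat) <- sprintf("g%d", 1:20)
  lp <- structure(list(features = feat,
                       y = factor(rep(c("pos", "other"), each = 20),
                                  levels = c("other", "pos")),
                       majority_fraction = rep(1, n), unit = "cluster"),
                  class = "labeled_profile")
  rep <- crossvalidate_auc(lp, folds = 5, seed = 2)
  expect_equal(rep$auc, 1)
  ## pooled AUC agrees with the rank-sum oracle on the same scores
  expect_equal(rep$auc, oracle_auc(rep$scores$label == "pos",
                                   rep$scores$score))
})

test_that("AUC of a score and its negation sum to one", {
  set.seed(22)
  pos <- rep(c(TRUE, FALSE), each = 30)
  s <- rnorm(60) + pos
  expect_equal(oracle_auc(pos, s) + oracle_auc(pos, -s), 1)
  r1 <- pROC::roc(response = pos, predictor = s, levels = c(FALSE, TRUE),
                  direction = "<", quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(r1)), oracle_auc(pos, s))
})

test_that("permuted labels give chance-level AUC", {
  set.seed(23)
  aucs <- vapply(1:10, function(i) {
    feat <- matrix(rnorm(200 * 30), 200, 30,
                   dimnames = list(sprintf("u%d", 1:200), sprintf("g%d", 1:30)))
    lp <- structure(list(features = feat,
                         y = factor(sample(rep(c("pos", "other"), each = 100)),
                                    levels = c("other", "pos")),
                         majority_fraction = rep(1, 200), unit = "cell"),
                    class = "labeled_profile")
    crossvalidate_auc(lp, folds = 10, seed = i)$auc
  }, numeric(1))
  ## single-run CV AUC under the null is noisy (out-of-fold scores pick up
  ## training noise), but every run stays far from the signal regime and
  ## the mean sits at chance
  expect_true(all(aucs > 0.3 & aucs < 0.7))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("stratified folds partition units and preserve class ratios", {
  set.seed(24)
  feat <- matrix(rnorm(55 * 10), 55, 10,
                 dimnames = list(NULL, sprintf("g%d", 1:10)))
  y <- factor(rep(c("other", "pos"), c(33, 22)), levels = c("other", "pos"))
  lp <- structure(list(features = feat, y = y,
                       majority_fraction = rep(1, 55), unit = "cluster"),
                  class = "labeled_profile")
  rep <- crossvalidate_auc(lp, folds = 5, seed = 9)
  f <- rep$scores$fold
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 55L)                      # every unit scored once
  expect_false(anyNA(rep$scores$score))
  tab <- table(f, rep$scores$label)
  ## per-fold class counts deviate by at most one unit from perfect ratio
  expect_lte(max(tab[, "pos"]) - min(tab[, "pos"]), 1L)
  expect_lte(max(tab[, "other"]) - min(tab[, "other"]), 1L)
})

test_that("degenerate classification inputs are rejected", {
  feat <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  lp1 <- structure(list(features = feat,
                        y = factor(rep("other", 10),
                                   levels = c("other", "pos")),
                        majority_fraction = rep(1, 10), unit = "cell"),
                   class = "labeled_profile")
  expect_error(crossvalidate_auc(lp1, folds = 5), "one class")
  expect_error(crossvalidate_auc(lp1, folds = 1), "folds")
})

test_that("labeled profiles align labels with clusters and cells", {
  sim <- simulate_dataset(sim_config(30, 200, zero_prob = 0.8, n_types = 2,
                                     n_marker_genes = 3, seed = 31))
  lp_cell <- labeled_profile(sim$expression, sim$cell_labels, "type2")
  expect_equal(nrow(lp_cell$features), 200L)
  expect_equal(levels(lp_cell$y), c("other", "type2"))
  expect_equal(sum(lp_cell$y == "type2"), sum(sim$cell_labels == "type2"))
  cl <- suppressMessages(partition(sim$embedding, 10, scale = 40, seed = 1))
  lp_cl <- labeled_profile(sim$expression, sim$cell_labels, "type2", cl)
  expect_equal(nrow(lp_cl$features), 10L)
  expect_error(labeled_profile(sim$expression, sim$cell_labels, "nosuch"),
               "not present")
})

test_that("k = n_cells reduces the cluster pipeline to the baseline exactly", {
  sim <- simulate_dataset(sim_config(40, 120, zero_prob = 0.85, n_types = 2,
                                     n_marker_genes = 5, seed = 32))
  sc <- suppressMessages(auc_vs_k_scan(sim$expression, sim$embedding,
                                       sim$cell_labels, "type1", ks = 120,
                                       folds = 5, seed = 7, scale = 40))
  expect_equal(sc$table$auc, sc$baseline_auc)
  expect_identical(sc$reports[["120"]]$scores$score,
                   sc$baseline_report$scores$score)
})

test_that("cluster profiles beat raw cells on dropout-heavy marker data", {
  sim <- simulate_dataset(sim_config(60, 800, zero_prob = 0.9, n_types = 2,
                                     n_marker_genes = 8, marker_shift = 1,
                                     seed = 33))
  sc <- suppressMessages(auc_vs_k_scan(sim$expression, sim$embedding,
                                       sim$cell_labels, "type1", ks = 40,
                                       folds = 10, seed = 5, scale = 50,
                                       min_cells = 10))
  expect_gt(sc$table$auc, sc$baseline_auc)
  expect_gt(sc$table$auc, 0.85)
})
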