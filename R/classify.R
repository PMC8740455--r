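# Cluster-profile-based cell-type classification with cross-validated AUC.

#' Majority-vote cluster labels from per-cell type labels
#'
#' Each cluster inherits the most frequent cell-type label among its member
#' cells; ties are broken by lexicographic label order and flagged by a
#' majority fraction of exactly the tied share.
#'
#' @param clustering A `cell_clustering`.
#' @param cell_labels Character vector of type labels named by cell id (or
#'   aligned with the clustering's cells).
#' @return Data frame with columns cluster, label, majority_fraction, size.
#' @export
label_clusters <- function(clustering, cell_labels) {
  stopifnot(inherits(clustering, "cell_clustering"))
  assign <- clustering$assignment
  if (!is.null(names(cell_labels))) {
    if (!all(names(assign) %in% names(cell_labels)))
      stop_invalid("cell_labels missing for some clustered cells")
    cell_labels <- cell_labels[names(assign)]
  } else if (length(cell_labels) != length(assign)) {
    stop_invalid("cell_labels length does not match the clustering")
  }
  keep <- !is.na(assign)
  res <- lapply(seq_len(clustering$k), function(cl) {
    labs <- cell_labels[keep & assign == cl]
    tab <- sort(table(labs), decreasing = TRUE)
    top <- tab[tab == tab[1]]
    winner <- sort(names(top))[1]               # lexicographic tie-break
    data.frame(cluster = cl, label = winner,
               majority_fraction = as.numeric(tab[1]) / length(labs),
               size = length(labs))
  })
  do.call(rbind, res)
}

#' Build a labeled feature profile for classification
#'
#' Assembles the units x genes feature matrix and a binary target for
#' cross-validated classification: cluster mean profiles labeled by majority
#' vote (when a clustering is given), or raw single cells labeled directly
#' (the nonclustering baseline, `clustering = NULL`).
#'
#' @param expr Genes x cells expression matrix.
#' @param cell_labels Per-cell type labels (named by cell id).
#' @param target The positive-class label (e.g. a cell type of interest).
#' @param clustering Optional `cell_clustering`; `NULL` for the single-cell
#'   baseline.
#' @return Object of class `labeled_profile`: list with `features` (units x
#'   genes dense matrix), `y` (factor, levels `c("other", target)`),
#'   `majority_fraction`, `unit` tag.
#' @export
labeled_profile <- function(expr, cell_labels, target, clustering = NULL) {
  expr <- validate_expression(expr)
  if (!is.null(names(cell_labels))) {
    if (!all(colnames(expr) %in% names(cell_labels)))
      stop_invalid("cell_labels missing for some cells")
    cell_labels <- cell_labels[colnames(expr)]
  } else if (length(cell_labels) != ncol(expr)) {
    stop_invalid("cell_labels length does not match the expression matrix")
  }
  if (!target %in% cell_labels)
    stop_invalid("target label \"", target, "\" not present in cell_labels")
  if (is.null(clustering)) {
    features <- t(as.matrix(expr))
    labels <- as.character(cell_labels)
    frac <- rep(1, length(labels))
  } else {
    features <- unclass(cluster_profile(expr, clustering))
    lab <- label_clusters(clustering, cell_labels)
    labels <- lab$label
    frac <- lab$majority_fraction
  }
  y <- factor(ifelse(labels == target, target, "other"),
              levels = c("other", target))
  structure(list(features = features, y = y, majority_fraction = frac,
                 unit = if (is.null(clustering)) "cell" else "cluster"),
            class = "labeled_profile")
}

# ridge-regularized logistic classifier behind a narrow train/score contract;
# feature selection (most variable genes) and standardization use training
# units only to avoid leakage
#' @noRd
ridge_train_score <- function(features, y, train, test, n_features, lambda) {
  xtr <- features[train, , drop = FALSE]
  v <- apply(xtr, 2, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_features, ncol(xtr)))]
  keep <- keep[v[keep] > 0]
  if (length(keep) < 2L) keep <- seq_len(min(2L, ncol(xtr)))
  mu <- colMeans(xtr[, keep, drop = FALSE])
  sg <- apply(xtr[, keep, drop = FALSE], 2, stats::sd)
  sg[sg == 0] <- 1
  std <- function(m) sweep(sweep(m[, keep, drop = FALSE], 2, mu), 2, sg, "/")
  fit <- suppressWarnings(glmnet::glmnet(std(features[train, , drop = FALSE]),
                                         y[train], family = "binomial",
                                         alpha = 0, lambda = lambda,
                                         standardize = FALSE))
  as.numeric(predict(fit, newx = std(features[test, , drop = FALSE]),
                     s = lambda, type = "link"))
}

#' Cross-validated AUC for a labeled profile
#'
#' Stratified k-fold cross-validation of a ridge-regularized logistic
#' classifier on the unit profiles; the most variable genes (default 500)
#' are selected within each training split. The AUC is computed from the
#' pooled out-of-fold scores.
#'
#' @param lp A [labeled_profile()].
#' @param folds Number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param n_features Number of most-variable genes used (default 500,
#'   capped at the gene count).
#' @param lambda Ridge penalty (default 0.01).
#' @return Object of class `cv_auc_report`: list with `auc` (pooled
#'   out-of-fold), `fold_auc` (per-fold values), `folds`, `scores` data
#'   frame (unit, fold, score, label).
#' @export
crossvalidate_auc <- function(lp, folds = 10L, seed = NULL,
                              n_features = 500L, lambda = 0.01) {
  stopifnot(inherits(lp, "labeled_profile"))
  folds <- as.integer(folds)
  if (is.na(folds) || folds < 2L) stop_invalid("folds must be >= 2")
  y <- lp$y
  if (length(unique(y)) < 2L)
    stop_invalid("undefined AUC: only one class present")
  if (min(table(y)) < 2L)
    stop_invalid("need at least 2 units per class")
  n <- length(y)
  with_seed(seed, {
    fold <- integer(n)
    for (cls in levels(y)) {                 # stratified assignment
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
    }
    score <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      test <- which(fold == f)
      if (!length(test)) next
      train <- which(fold != f)
      if (length(unique(y[train])) < 2L)
        stop_invalid("a training split lost one class; reduce folds")
      score[test] <- ridge_train_score(lp$features, y, train, test,
                                       n_features, lambda)
    }
    pos <- levels(y)[2]
    auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                          levels = levels(y), direction = "<",
                                          quiet = TRUE)))
    fold_auc <- vapply(seq_len(folds), function(f) {
      sel <- fold == f
      if (length(unique(y[sel])) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(response = y[sel], predictor = score[sel],
                                     levels = levels(y), direction = "<",
                                     quiet = TRUE)))
    }, numeric(1))
    structure(list(auc = auc, fold_auc = fold_auc, folds = folds,
                   scores = data.frame(unit = rownames(lp$features) %||%
                                         seq_len(n),
                                       fold = fold, score = score,
                                       label = as.character(y)),
                   unit = lp$unit, pos_level = pos),
              class = "cv_auc_report")
  })
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_auc_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated AUC (%s level): %.3f\n",
              x$folds, x$unit, x$auc))
  invisible(x)
}

#' Classification AUC across a series of cluster numbers
#'
#' For each k: partition (one shared merge path), build cluster-mean
#' profiles, derive majority-vote binary labels, and cross-validate the
#' classifier; the raw single-cell profile with per-cell labels provides the
#' nonclustering baseline under the same seed. With k equal to the number of
#' cells the cluster pipeline reduces to the baseline exactly.
#'
#' @inheritParams crossvalidate_auc
#' @inheritParams partition
#' @param expr Genes x cells expression matrix.
#' @param cell_labels Per-cell type labels (named by cell id).
#' @param target Positive-class label.
#' @param ks Cluster counts to evaluate.
#' @param min_cells When `> 0`, undersized clusters are absorbed into their
#'   nearest neighbour before profiling (see [filter_small_clusters()]);
#'   mini-clusters of a handful of cells carry profiles nearly as noisy as
#'   single cells and dilute the classifier. Default 0 (off), so that
#'   `ks = n_cells` reduces exactly to the baseline.
#' @return Object of class `auc_scan`: list with `table` (data frame k,
#'   k_effective, auc), `baseline_auc`, `folds`, `reports` (per-k
#'   `cv_auc_report`), `baseline_report`.
#' @export
auc_vs_k_scan <- function(expr, emb, cell_labels, target, ks, folds = 10L,
                          seed = NULL, cutoff = 3, scale = "auto",
                          mode = "inverted-distance", n_features = 500L,
                          lambda = 0.01, min_cells = 0L) {
  expr <- validate_expression(expr)
  series <- partition_series(emb, ks, cutoff = cutoff, scale = scale,
                             mode = mode, seed = seed)
  k_eff <- integer(length(series$ks))
  reports <- lapply(seq_along(series$ks), function(i) {
    cl <- series[[series$ks[i]]]
    if (min_cells > 0L)
      cl <- filter_small_clusters(cl, min_cells = min_cells, mode = "merge")
    k_eff[i] <<- cl$k
    lp <- labeled_profile(expr, cell_labels, target, clustering = cl)
    crossvalidate_auc(lp, folds = folds, seed = seed,
                      n_features = n_features, lambda = lambda)
  })
  names(reports) <- as.character(series$ks)
  base_lp <- labeled_profile(expr, cell_labels, target, clustering = NULL)
  base <- crossvalidate_auc(base_lp, folds = folds, seed = seed,
                            n_features = n_features, lambda = lambda)
  structure(list(
    table = data.frame(k = series$ks, k_effective = k_eff,
                       auc = vapply(reports, function(r) r$auc, numeric(1))),
    baseline_auc = base$auc, folds = folds, reports = reports,
    baseline_report = base
  ), class = "auc_scan")
}

#' @export
print.auc_scan <- function(x, ...) {
  cat(sprintf("Cluster-profile AUC over k = %s\n",
              paste(x$table$k, collapse = ", ")))
  print(x$table, row.names = FALSE)
  cat(sprintf("single-cell baseline AUC: %.3f\n", x$baseline_auc))
  invisible(x)
}

#' @param x An `auc_scan`.
#' @param ... Passed to [graphics::plot()].
#' @rdname auc_vs_k_scan
#' @export
plot.auc_scan <- function(x, ...) {
  graphics::plot(x$table$k, x$table$auc, type = "b", pch = 16, ylim = c(0, 1),
                 xlab = "number of clusters k", ylab = "AUC", ...)
  graphics::abline(h = x$baseline_auc, lty = 2, col = "firebrick")
  invisible(x)
}
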