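# Cluster-level and single-cell gene-gene correlation with BH FDR control.

#' Within-cluster mean expression profile
#'
#' Averages each gene's expression over the cells of each cluster, zeros
#' included; the k cluster means then serve as the observations for
#' gene-gene correlation. The size-weighted mean of the cluster means
#' reproduces the global per-gene mean exactly.
#'
#' @param expr Genes x cells expression matrix (dense or sparse).
#' @param clustering A `cell_clustering`; cells are matched to the columns
#'   of `expr` by id (unassigned cells are excluded).
#' @return Object of class `cluster_profile`: k x genes dense matrix of
#'   means, with attributes `sizes` (cells per cluster) and `unit` =
#'   `"cluster"`.
#' @export
cluster_profile <- function(expr, clustering) {
  expr <- validate_expression(expr)
  stopifnot(inherits(clustering, "cell_clustering"))
  assign <- clustering$assignment
  if (!all(names(assign) %in% colnames(expr)))
    stop_invalid("clustering contains cells absent from the expression matrix")
  assign <- assign[!is.na(assign)]
  ind <- Matrix::sparseMatrix(i = match(names(assign), colnames(expr)),
                              j = assign, x = 1,
                              dims = c(ncol(expr), clustering$k))
  sizes <- clustering$sizes
  if (any(sizes < 1L)) stop("internal error: empty cluster in profile")
  sums <- as.matrix(expr %*% ind)                    # genes x k
  prof <- t(sweep(sums, 2, sizes, "/"))              # k x genes
  dimnames(prof) <- list(paste0("cluster", seq_len(clustering$k)),
                         rownames(expr))
  structure(prof, sizes = sizes, unit = "cluster", class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("Cluster profile: %d cluster(s) x %d gene(s)\n", nrow(x), ncol(x)))
  invisible(x)
}

# core correlation test: Pearson r with the Gaussian-family linear-model
# slope p-value, which equals the classical correlation t-test
# t = r * sqrt((n-2)/(1-r^2)) on n-2 df; Spearman ranks then reuses it.
# Optional weights give the weighted Pearson coefficient (same t reference,
# an approximation); weighting by unit size restores null calibration when
# the units are cluster means of very different cell counts, whose shared
# variance pattern otherwise inflates the null tail of r.
#' @noRd
cor_test_core <- function(x, y, method = "pearson", weights = NULL) {
  n <- length(x)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  if (is.null(weights)) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_, n = n, status = "degenerate"))
    r <- stats::cor(x, y)
  } else {
    w <- weights / sum(weights)
    mx <- sum(w * x); my <- sum(w * y)
    vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
    if (vx == 0 || vy == 0)
      return(list(r = NA_real_, p = NA_real_, n = n, status = "degenerate"))
    r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  }
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n, status = "ok")
}

#' Correlation test for one gene pair
#'
#' Pearson (or Spearman, via rank transform) correlation with a two-sided
#' p-value from the Gaussian linear-model slope test - identical to the
#' classical correlation t-test with `t = r * sqrt((n-2)/(1-r^2))` on `n-2`
#' degrees of freedom. Constant input yields a degenerate result (no valid
#' test statistic exists).
#'
#' @param x,y Numeric vectors of equal length `>= 3` (values of the two
#'   genes across units - cells or cluster means).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param weights Optional positive unit weights (e.g. cluster cell counts);
#'   gives the weighted Pearson coefficient with the same t reference.
#' @return List with `r`, `p`, `n`, `status` (`"ok"` or `"degenerate"`).
#' @examples
#' correlate_pair(1:10, 2 * (1:10) + 1)   # r = 1, p = 0
#' @export
correlate_pair <- function(x, y, method = c("pearson", "spearman"),
                           weights = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 3L) stop_invalid("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_invalid("x and y must be finite")
  if (!is.null(weights)) {
    if (length(weights) != length(x) || any(!is.finite(weights)) ||
        any(weights <= 0))
      stop_invalid("weights must be positive and match the vector length")
    weights <- as.numeric(weights)
  }
  cor_test_core(as.numeric(x), as.numeric(y), method, weights)
}

# canonicalize correlate_pairs input to a units x genes matrix + method tag
#' @noRd
as_unit_matrix <- function(x) {
  if (inherits(x, "cluster_profile")) {
    list(values = unclass(x), tag = "cluster")
  } else {
    x <- validate_expression(x)
    list(values = t(as.matrix(x)), tag = "cell")
  }
}

#' Correlation tests for a list of gene pairs with BH FDR control
#'
#' Runs [correlate_pair()] for every requested pair on either a
#' [cluster_profile()] (method tag `"cluster"`) or a raw genes x cells
#' expression matrix (method tag `"cell"`), then applies Benjamini-Hochberg
#' adjustment across all non-degenerate tests. Pairs naming genes absent
#' from the matrix are skipped with status `"missing"`; degenerate pairs
#' (a constant gene) are excluded from the BH denominator.
#'
#' @param x A `cluster_profile` or genes x cells expression matrix.
#' @param pairs Two-column data frame / matrix of gene ids.
#' @param alpha Significance threshold on the BH q-value (default 0.05).
#' @param spearman Also report the Spearman coefficient (default TRUE).
#' @param weight_by_size Weight cluster units by their cell counts (requires
#'   a `cluster_profile` input). The default (`FALSE`) treats every cluster
#'   as one observation, matching the plain per-cluster averaging approach;
#'   weighting restores null calibration when cluster sizes are very uneven,
#'   because the shared size-driven variance pattern of the means otherwise
#'   inflates the null tail of r (see the methods vignette).
#' @return A data frame (class `gene_pair_cor`) sorted by p-value with
#'   columns gene_a, gene_b, method, n_units, r, r_spearman, p, q,
#'   significant, status.
#' @export
correlate_pairs <- function(x, pairs, alpha = 0.05, spearman = TRUE,
                            weight_by_size = FALSE) {
  um <- as_unit_matrix(x)
  vals <- um$values
  weights <- NULL
  if (weight_by_size) {
    if (um$tag != "cluster")
      stop_invalid("weight_by_size requires a cluster_profile input")
    weights <- as.numeric(attr(x, "sizes"))
  }
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 1L) stop_invalid("empty gene-pair list")
  ga <- as.character(pairs[[1]]); gb <- as.character(pairs[[2]])
  ia <- match(ga, colnames(vals)); ib <- match(gb, colnames(vals))
  n_missing <- sum(is.na(ia) | is.na(ib))
  if (n_missing == nrow(pairs))
    stop_invalid("none of the pair genes are present in the matrix")
  if (n_missing > 0)
    message(n_missing, " pair(s) skipped: gene id(s) not in the matrix")
  n_units <- nrow(vals)
  if (n_units < 3L) stop_invalid("need at least 3 units for correlation")
  res <- lapply(seq_along(ia), function(i) {
    if (is.na(ia[i]) || is.na(ib[i]))
      return(data.frame(r = NA_real_, r_spearman = NA_real_, p = NA_real_,
                        status = "missing"))
    xv <- vals[, ia[i]]; yv <- vals[, ib[i]]
    ct <- cor_test_core(xv, yv, "pearson", weights)
    rs <- if (spearman && ct$status == "ok")
      cor_test_core(xv, yv, "spearman", weights)$r else NA_real_
    data.frame(r = ct$r, r_spearman = rs, p = ct$p, status = ct$status)
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene_a = ga, gene_b = gb, method = um$tag,
                    n_units = n_units, r = res$r, r_spearman = res$r_spearman,
                    p = res$p, q = NA_real_, significant = FALSE,
                    status = res$status)
  ok <- out$status == "ok"
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$significant <- !is.na(out$q) & out$q < alpha
  out <- out[order(out$p, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("gene_pair_cor", "data.frame")
  out
}

#' Cluster-level versus single-cell correlation comparison
#'
#' Tests the same gene pairs twice - across raw single cells, and across the
#' k cluster means of a fresh [partition()] - and reports both estimates
#' side by side with a sign-agreement flag, mirroring the standard
#' cluster-vs-cell scatter diagnostic.
#'
#' @inheritParams partition
#' @param expr Genes x cells expression matrix.
#' @param pairs Two-column gene-pair table.
#' @param alpha BH q-value threshold (default 0.05).
#' @param min_cells When `> 0`, clusters below this size are absorbed into
#'   their nearest neighbour before profiling ([filter_small_clusters()]);
#'   means over a handful of cells are nearly as noisy as single cells and
#'   act as leverage points in the correlation. Default 0 (off), so
#'   `k = n_cells` reproduces the single-cell result exactly.
#' @return Data frame (class `cluster_cell_comparison`) with per-pair
#'   r/p/q/significance for both methods and `agreement`
#'   (`sign(r_cell) == sign(r_cluster)`); attributes `n_sig_cell`,
#'   `n_sig_cluster`, `n_sig_both`, `k`, `k_effective`.
#' @export
compare_cluster_vs_cell <- function(expr, emb, pairs, k, cutoff = 3,
                                    scale = "auto", mode = "inverted-distance",
                                    alpha = 0.05, seed = NULL, min_cells = 0L) {
  expr <- validate_expression(expr)
  cell_res <- correlate_pairs(expr, pairs, alpha = alpha)
  cl <- partition(emb, k, cutoff = cutoff, scale = scale, mode = mode,
                  seed = seed)
  if (min_cells > 0L)
    cl <- filter_small_clusters(cl, min_cells = min_cells, mode = "merge")
  prof <- cluster_profile(expr, cl)
  clus_res <- correlate_pairs(prof, pairs, alpha = alpha)
  key <- function(d) paste(d$gene_a, d$gene_b, sep = "\r")
  m <- match(key(cell_res), key(clus_res))
  out <- data.frame(
    gene_a = cell_res$gene_a, gene_b = cell_res$gene_b,
    r_cell = cell_res$r, p_cell = cell_res$p, q_cell = cell_res$q,
    sig_cell = cell_res$significant,
    r_cluster = clus_res$r[m], p_cluster = clus_res$p[m],
    q_cluster = clus_res$q[m], sig_cluster = clus_res$significant[m],
    status = ifelse(cell_res$status == "ok" & clus_res$status[m] == "ok",
                    "ok", "degenerate")
  )
  out$agreement <- sign(out$r_cell) == sign(out$r_cluster)
  out <- out[order(out$p_cluster, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  attr(out, "k_effective") <- cl$k
  attr(out, "n_sig_cell") <- sum(out$sig_cell, na.rm = TRUE)
  attr(out, "n_sig_cluster") <- sum(out$sig_cluster, na.rm = TRUE)
  attr(out, "n_sig_both") <- sum(out$sig_cell & out$sig_cluster, na.rm = TRUE)
  class(out) <- c("cluster_cell_comparison", "data.frame")
  out
}

#' @export
print.cluster_cell_comparison <- function(x, ...) {
  cat(sprintf("Cluster (k = %d) vs cell correlation on %d pair(s):\n",
              attr(x, "k"), nrow(x)))
  cat(sprintf("  significant: cluster %d, cell %d, both %d; sign agreement %d/%d\n",
              attr(x, "n_sig_cluster"), attr(x, "n_sig_cell"),
              attr(x, "n_sig_both"), sum(x$agreement, na.rm = TRUE),
              sum(!is.na(x$agreement))))
  NextMethod()
}

#' Stability of top gene pairs across cluster numbers
#'
#' Selects the `top_n` pairs with the smallest p-values at `reference_k`
#' (default 100 clusters) and recomputes their correlation at every k in the
#' series (one shared merge path), to identify the range of cluster numbers
#' over which r and p are stable.
#'
#' @inheritParams compare_cluster_vs_cell
#' @param ks Cluster counts to evaluate; must contain `reference_k`. A k
#'   equal to the number of cells yields the single-cell baseline column.
#' @param reference_k Cluster count used to rank pairs (default 100).
#' @param top_n Number of top pairs to track (default 10; truncated with a
#'   warning when fewer testable pairs exist).
#' @param min_cells As in [compare_cluster_vs_cell()]; applied per k.
#' @return Data frame (class `stability_scan`) with columns k, rank, gene_a,
#'   gene_b, r, r_spearman, p; attribute `reference_k`.
#' @export
stability_scan <- function(expr, emb, pairs, ks, reference_k = 100L,
                           top_n = 10L, cutoff = 3, scale = "auto",
                           mode = "inverted-distance", alpha = 0.05,
                           seed = NULL, min_cells = 0L) {
  expr <- validate_expression(expr)
  ks <- sort(unique(as.integer(ks)))
  reference_k <- as.integer(reference_k)
  if (!reference_k %in% ks)
    stop_invalid("reference_k (", reference_k, ") must be one of ks")
  series <- partition_series(emb, ks, cutoff = cutoff, scale = scale,
                             mode = mode, seed = seed)
  res_by_k <- lapply(ks, function(k) {
    cl <- series[[k]]
    if (min_cells > 0L && k < series$n_cells)
      cl <- filter_small_clusters(cl, min_cells = min_cells, mode = "merge")
    correlate_pairs(cluster_profile(expr, cl), pairs, alpha = alpha)
  })
  names(res_by_k) <- as.character(ks)
  ref <- res_by_k[[as.character(reference_k)]]
  ref <- ref[ref$status == "ok", ]
  if (nrow(ref) < top_n) {
    warning("only ", nrow(ref), " testable pair(s) at reference k; truncating")
    top_n <- nrow(ref)
  }
  top <- ref[seq_len(top_n), c("gene_a", "gene_b")]
  out <- do.call(rbind, lapply(ks, function(k) {
    rk <- res_by_k[[as.character(k)]]
    m <- match(paste(top$gene_a, top$gene_b), paste(rk$gene_a, rk$gene_b))
    data.frame(k = k, rank = seq_len(top_n), gene_a = top$gene_a,
               gene_b = top$gene_b, r = rk$r[m],
               r_spearman = rk$r_spearman[m], p = rk$p[m])
  }))
  rownames(out) <- NULL
  attr(out, "reference_k") <- reference_k
  class(out) <- c("stability_scan", "data.frame")
  out
}

#' @param x A `stability_scan` result.
#' @param what `"r"` or `"p"` (plotted as -log10 p).
#' @param ... Passed to [graphics::matplot()].
#' @rdname stability_scan
#' @export
plot.stability_scan <- function(x, what = c("r", "p"), ...) {
  what <- match.arg(what)
  wide <- tapply(if (what == "r") x$r else -log10(x$p),
                 list(x$k, x$rank), identity)
  graphics::matplot(as.numeric(rownames(wide)), wide, type = "b", pch = 16,
                    xlab = "number of clusters k",
                    ylab = if (what == "r") "Pearson r" else "-log10 p", ...)
  invisible(x)
}
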