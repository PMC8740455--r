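# Clustering objects and the greedy merge-to-k partitioner.

#' Construct a cell clustering object
#'
#' Normalizes an assignment vector into a `cell_clustering`: labels are
#' re-indexed 1..k by descending cluster size (ties keep first-appearance
#' order, so singleton clusters stay in cell order), centroids are the
#' arithmetic means of member coordinates, and `NA` marks cells left
#' unassigned by filtering.
#'
#' @param assignment Integer/factor vector of cluster labels per cell (`NA`
#'   allowed for unassigned cells); names are taken as cell ids.
#' @param coords Optional n x 2 coordinate matrix for centroid computation.
#' @return Object of class `cell_clustering`: list with `k`, `assignment`
#'   (integer 1..k, named by cell id), `sizes`, `centroids` (k x 2 or NULL),
#'   `ids`.
#' @export
as_clustering <- function(assignment, coords = NULL) {
  new_clustering(assignment, coords)
}

#' @noRd
new_clustering <- function(assignment, coords = NULL) {
  ids <- names(assignment)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)[, 1:2, drop = FALSE]
    storage.mode(coords) <- "double"
    if (length(assignment) != nrow(coords))
      stop_invalid("assignment length does not match coordinate rows")
    if (is.null(ids)) ids <- rownames(coords)
  }
  if (is.null(ids)) ids <- sprintf("c%d", seq_along(assignment))
  av <- as.integer(as.factor(assignment))          # dense temporary labels
  assigned <- !is.na(av)
  if (!any(assigned)) stop_invalid("clustering has no assigned cells")
  sizes0 <- tabulate(av[assigned])
  first0 <- match(seq_along(sizes0), av)
  ord <- order(-sizes0, first0)                    # size desc, stable
  relab <- integer(length(sizes0)); relab[ord] <- seq_along(ord)
  out_assign <- ifelse(assigned, relab[av], NA_integer_)
  names(out_assign) <- ids
  k <- length(sizes0)
  sizes <- tabulate(out_assign[assigned], nbins = k)
  centroids <- NULL
  if (!is.null(coords)) {
    centroids <- rowsum(coords[assigned, , drop = FALSE],
                        out_assign[assigned]) / sizes
    rownames(centroids) <- seq_len(k)
  }
  structure(list(k = k, assignment = out_assign, sizes = sizes,
                 centroids = centroids, ids = ids),
            class = "cell_clustering")
}

#' @export
print.cell_clustering <- function(x, ...) {
  na <- sum(is.na(x$assignment))
  cat(sprintf("Cell clustering: %d cluster(s) over %d cells%s\n", x$k,
              length(x$assignment),
              if (na) sprintf(" (%d unassigned)", na) else ""))
  cat(sprintf("  sizes: min %d, median %g, max %d\n",
              min(x$sizes), median(x$sizes), max(x$sizes)))
  invisible(x)
}

#' @export
summary.cell_clustering <- function(object, min_cells = 10L, ...) {
  cells_per_cluster_summary(object, min_cells = min_cells)
}

#' @export
plot.cell_clustering <- function(x, coords = NULL, ...) {
  if (is.null(coords)) coords <- x$centroids
  if (is.null(coords)) stop_invalid("no coordinates available for plotting")
  if (nrow(coords) == length(x$assignment)) {
    graphics::plot(coords, col = x$assignment, pch = 16, cex = 0.5,
                   xlab = "x", ylab = "y", ...)
    if (!is.null(x$centroids))
      graphics::points(x$centroids, pch = 3, cex = 1.2)
  } else {
    graphics::symbols(x$centroids[, 1], x$centroids[, 2],
                      circles = sqrt(x$sizes), inches = 0.15,
                      xlab = "x", ylab = "y", ...)
  }
  invisible(x)
}

# cluster-level adjacency matrix: TRUE where >= 1 inter-cluster graph edge
#' @noRd
cluster_adjacency <- function(assignment, graph, N) {
  A <- matrix(FALSE, N, N)
  if (igraph::ecount(graph) > 0L) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    ca <- assignment[el[, 1]]; cb <- assignment[el[, 2]]
    keep <- ca != cb
    if (any(keep)) {
      A[cbind(ca[keep], cb[keep])] <- TRUE
      A[cbind(cb[keep], ca[keep])] <- TRUE
    }
  }
  A
}

#' Greedily merge adjacent clusters down to exactly k
#'
#' Repeats N - k times: among cluster pairs connected by at least one
#' inter-cluster graph edge, merge the pair with the smallest centroid
#' Euclidean distance (ties broken by the lexicographically smallest label
#' pair); the merged centroid is recomputed from the member cells. When no
#' adjacent pair remains while N > k (disconnected components), the globally
#' closest centroid pair is merged instead.
#'
#' @param clustering A `cell_clustering` with `N >= k` clusters and no
#'   unassigned cells.
#' @param cg The [build_cell_graph()] used to define cluster adjacency.
#' @param k Target number of clusters.
#' @return A `cell_clustering` with exactly `k` clusters, labels 1..k by
#'   descending size.
#' @seealso [partition()] for the full pipeline, [partition_series()] for
#'   snapshots of one merge path at several k.
#' @export
merge_to_k <- function(clustering, cg, k) {
  stopifnot(inherits(clustering, "cell_clustering"), inherits(cg, "cell_graph"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > clustering$k)
    stop_invalid("k must lie in 1..N (N = ", clustering$k, " clusters)")
  merge_path(clustering, cg, targets = k)[[1]]
}

# walk one merge path from N down to min(targets), snapshotting at each
# requested cluster count; returns named list of cell_clustering objects
#' @noRd
merge_path <- function(clustering, cg, targets) {
  if (anyNA(clustering$assignment))
    stop_invalid("cannot merge a clustering with unassigned cells")
  targets <- sort(unique(as.integer(targets)), decreasing = TRUE)
  N <- clustering$k
  if (targets[1] > N) stop_invalid("target k exceeds cluster count N = ", N)
  coords <- cg$coords
  assign0 <- clustering$assignment
  csum <- rowsum(coords, assign0)
  csize <- as.numeric(tabulate(assign0, nbins = N))
  cent <- csum / csize
  active <- rep(TRUE, N)
  A <- cluster_adjacency(assign0, cg$graph, N)
  rep_of <- seq_len(N)                      # merge chain: cluster -> survivor

  row_best <- function(i) {
    js <- which(A[i, ] & active)
    if (!length(js)) return(list(d = Inf, j = NA_integer_))
    d <- sqrt((cent[js, 1] - cent[i, 1])^2 + (cent[js, 2] - cent[i, 2])^2)
    m <- which.min(d)                       # first minimum: smallest label
    list(d = d[m], j = js[m])
  }
  nnd <- rep(Inf, N); nnb <- rep(NA_integer_, N)
  for (i in seq_len(N)) {
    rb <- row_best(i); nnd[i] <- rb$d; nnb[i] <- rb$j
  }

  snapshot <- function() {
    r <- rep_of
    repeat {                               # resolve merge chains
      r2 <- rep_of[r]
      if (identical(r2, r)) break
      r <- r2
    }
    new_clustering(setNames(r[assign0], names(assign0)), coords)
  }

  out <- list()
  n_active <- N
  if (n_active %in% targets) out[[as.character(n_active)]] <- snapshot()
  while (n_active > min(targets)) {
    i0 <- which.min(nnd)                   # smallest label wins ties
    if (is.finite(nnd[i0])) {
      a <- min(i0, nnb[i0]); b <- max(i0, nnb[i0])
    } else {
      ## no adjacent pair left: globally closest active centroid pair
      act <- which(active)
      D <- cross_dist2(cent[act, , drop = FALSE], cent[act, , drop = FALSE])
      D[lower.tri(D, diag = TRUE)] <- Inf
      hit <- which(D == min(D), arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      a <- act[hit[1, 1]]; b <- act[hit[1, 2]]
    }
    ## merge b into a
    csum[a, ] <- csum[a, ] + csum[b, ]
    csize[a] <- csize[a] + csize[b]
    cent[a, ] <- csum[a, ] / csize[a]
    active[b] <- FALSE
    rep_of[rep_of == b] <- a
    merged_adj <- A[a, ] | A[b, ]
    merged_adj[c(a, b)] <- FALSE
    A[a, ] <- merged_adj; A[, a] <- merged_adj
    A[b, ] <- FALSE; A[, b] <- FALSE
    nnd[b] <- Inf; nnb[b] <- NA_integer_
    ## refresh nearest-partner caches
    rb <- row_best(a); nnd[a] <- rb$d; nnb[a] <- rb$j
    stale <- which(active & (nnb == a | nnb == b) & seq_len(N) != a)
    for (i in stale) {
      rb <- row_best(i); nnd[i] <- rb$d; nnb[i] <- rb$j
    }
    touch <- which(active & A[, a] & seq_len(N) != a)
    touch <- setdiff(touch, stale)
    if (length(touch)) {
      d_new <- sqrt((cent[touch, 1] - cent[a, 1])^2 +
                    (cent[touch, 2] - cent[a, 2])^2)
      better <- d_new < nnd[touch] |
        (d_new == nnd[touch] & a < nnb[touch])   # keep smallest-label partner
      if (any(better)) {
        nnd[touch[better]] <- d_new[better]
        nnb[touch[better]] <- a
      }
    }
    n_active <- n_active - 1L
    if (n_active %in% targets) out[[as.character(n_active)]] <- snapshot()
  }
  out[as.character(targets)]
}

#' Partition cells into exactly k clusters on an embedding graph
#'
#' The full k-partitioning pipeline: scale the embedding, build the
#' distance-threshold graph, over-segment with Louvain into N > k
#' communities, and greedily merge adjacent communities by centroid distance
#' until exactly k clusters remain. With `k` equal to the number of cells the
#' partition is the singleton clustering (each cell its own cluster).
#'
#' @param emb n x 2 embedding (cell ids as rownames) or data frame.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param cutoff Edge distance cutoff in scaled units (default 3).
#' @param scale Target coordinate half-range or `"auto"`; see
#'   [scale_embedding()].
#' @param mode Edge weighting mode; see [build_cell_graph()].
#' @param seed Optional RNG seed (Louvain reproducibility).
#' @return A `cell_clustering` with exactly `k` non-empty clusters and every
#'   cell assigned; attributes `N` (over-segmentation count), `resolution`,
#'   and `graph` (the `cell_graph`).
#' @examples
#' emb <- cbind(x = rnorm(300), y = rnorm(300))
#' rownames(emb) <- paste0("c", 1:300)
#' cl <- partition(emb, k = 10, scale = 50, seed = 1)
#' cl$k
#' @export
partition <- function(emb, k, cutoff = 3, scale = "auto",
                      mode = "inverted-distance", seed = NULL) {
  emb <- as_embedding(emb)
  n <- nrow(emb)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n)
    stop_invalid("k must lie in 1..n_cells (n = ", n, ")")
  if (k == n) {
    out <- new_clustering(setNames(seq_len(n), rownames(emb)), emb)
    attr(out, "N") <- n; attr(out, "resolution") <- NA_real_
    return(out)
  }
  semb <- scale_embedding(emb, scale)
  cg <- build_cell_graph(semb, cutoff = cutoff, mode = mode)
  over <- louvain_oversegment(cg, k, seed = seed)
  out <- merge_to_k(over, cg, k)
  attr(out, "N") <- attr(over, "N")
  attr(out, "resolution") <- attr(over, "resolution")
  attr(out, "graph") <- cg
  out
}

#' Partition a cell embedding at a series of k values along one merge path
#'
#' Computes a single Louvain over-segmentation with N greater than the
#' largest requested k, then walks one greedy merge path from N down to the
#' smallest k, snapshotting the assignment at every requested k. By
#' construction the snapshots are nested: every cluster at a smaller k is a
#' union of clusters at any larger k in the series.
#'
#' @inheritParams partition
#' @param ks Ascending vector of cluster counts.
#' @return Object of class `cluster_series`: list with `ks`, `clusterings`
#'   (named list of `cell_clustering`), `N`, `resolution`.
#' @examples
#' emb <- cbind(x = rnorm(400), y = rnorm(400))
#' rownames(emb) <- paste0("c", 1:400)
#' ser <- partition_series(emb, ks = c(5, 10, 20), scale = 40, seed = 1)
#' ser$ks
#' @export
partition_series <- function(emb, ks, cutoff = 3, scale = "auto",
                             mode = "inverted-distance", seed = NULL) {
  emb <- as_embedding(emb)
  n <- nrow(emb)
  ks <- sort(unique(as.integer(ks)))
  if (any(is.na(ks)) || any(ks < 1L) || any(ks > n))
    stop_invalid("all ks must lie in 1..n_cells (n = ", n, ")")
  ks_main <- ks[ks < n]
  clusterings <- list()
  N <- n; resolution <- NA_real_
  if (length(ks_main)) {
    semb <- scale_embedding(emb, scale)
    cg <- build_cell_graph(semb, cutoff = cutoff, mode = mode)
    over <- louvain_oversegment(cg, max(ks_main), seed = seed)
    N <- attr(over, "N"); resolution <- attr(over, "resolution")
    clusterings <- merge_path(over, cg, targets = ks_main)
  }
  if (n %in% ks) {
    clusterings[[as.character(n)]] <-
      new_clustering(setNames(seq_len(n), rownames(emb)), emb)
  }
  clusterings <- clusterings[as.character(ks)]
  structure(list(ks = ks, clusterings = clusterings, N = N,
                 resolution = resolution, n_cells = n),
            class = "cluster_series")
}

#' @export
print.cluster_series <- function(x, ...) {
  cat(sprintf("Cluster series over %d cells: k = %s (over-segmented at N = %d)\n",
              x$n_cells, paste(x$ks, collapse = ", "), x$N))
  invisible(x)
}

#' @export
`[[.cluster_series` <- function(x, i) {
  cl <- unclass(x)$clusterings
  if (is.numeric(i) && !as.character(i) %in% names(cl) && i <= length(cl))
    return(cl[[i]])
  cl[[as.character(i)]]
}

#' Cluster-size diagnostics
#'
#' Tabulates cells per cluster and compares with the expected size
#' n_assigned_cells / k; clusters below `min_cells` are candidates for
#' removal or merging (see [filter_small_clusters()]).
#'
#' @param clustering A `cell_clustering`.
#' @param min_cells Size threshold for the small-cluster count (default 10).
#' @return Object of class `cluster_size_summary`: list with `table`
#'   (data frame cluster, size), `expected`, `min`, `median`, `max`,
#'   `n_below`, `min_cells`.
#' @export
cells_per_cluster_summary <- function(clustering, min_cells = 10L) {
  stopifnot(inherits(clustering, "cell_clustering"))
  sizes <- clustering$sizes
  n_assigned <- sum(sizes)
  structure(list(
    table = data.frame(cluster = seq_along(sizes), size = sizes),
    expected = n_assigned / clustering$k,
    min = min(sizes), median = median(sizes), max = max(sizes),
    n_below = sum(sizes < min_cells), min_cells = as.integer(min_cells)
  ), class = "cluster_size_summary")
}

#' @export
print.cluster_size_summary <- function(x, ...) {
  cat(sprintf("Cells per cluster: expected %.2f; observed min %d, median %g, max %d\n",
              x$expected, x$min, x$median, x$max))
  cat(sprintf("  clusters below %d cells: %d\n", x$min_cells, x$n_below))
  invisible(x)
}

#' Remove or absorb undersized clusters
#'
#' Clusters holding fewer than `min_cells` cells carry too few observations
#' for a stable mean profile. `mode = "merge"` absorbs each undersized
#' cluster into its nearest-centroid neighbour (iterating until every
#' remaining cluster reaches the threshold or one cluster remains);
#' `mode = "drop"` marks their cells unassigned and reduces k.
#'
#' @param clustering A `cell_clustering` with centroids.
#' @param min_cells Minimum acceptable cluster size (default 10).
#' @param mode `"merge"` (default) or `"drop"`.
#' @return A `cell_clustering`; attribute `filtered` records the sizes of
#'   the affected input clusters.
#' @export
filter_small_clusters <- function(clustering, min_cells = 10L,
                                  mode = c("merge", "drop")) {
  stopifnot(inherits(clustering, "cell_clustering"))
  mode <- match.arg(mode)
  min_cells <- as.integer(min_cells)
  if (is.na(min_cells) || min_cells < 1L) stop_invalid("min_cells must be >= 1")
  if (all(clustering$sizes >= min_cells)) {
    attr(clustering, "filtered") <- integer(0)
    return(clustering)
  }
  assign <- clustering$assignment
  if (mode == "drop") {
    small <- which(clustering$sizes < min_cells)
    assign[assign %in% small] <- NA_integer_
    if (all(is.na(assign)))
      stop_invalid("dropping clusters below ", min_cells, " cells removes all cells")
    out <- new_clustering(assign, centroid_coords(clustering))
    attr(out, "filtered") <- clustering$sizes[small]
    return(out)
  }
  ## merge mode: iteratively absorb the smallest undersized cluster
  if (is.null(clustering$centroids))
    stop_invalid("merge mode requires cluster centroids")
  sizes <- clustering$sizes
  cent <- clustering$centroids
  csum <- cent * sizes
  active <- rep(TRUE, clustering$k)
  relab <- seq_len(clustering$k)
  affected <- integer(0)
  repeat {
    act <- which(active)
    if (length(act) <= 1L) break
    small <- act[sizes[act] < min_cells]
    if (!length(small)) break
    b <- small[which.min(sizes[small])]
    others <- setdiff(act, b)
    d <- sqrt((cent[others, 1] - cent[b, 1])^2 +
              (cent[others, 2] - cent[b, 2])^2)
    a <- others[which.min(d)]
    csum[a, ] <- csum[a, ] + csum[b, ]
    sizes[a] <- sizes[a] + sizes[b]
    cent[a, ] <- csum[a, ] / sizes[a]
    active[b] <- FALSE
    relab[relab == b] <- a
    affected <- c(affected, b)
  }
  out <- new_clustering(setNames(relab[assign], names(assign)),
                        centroid_coords(clustering))
  attr(out, "filtered") <- clustering$sizes[affected]
  out
}

# per-cell coordinates are not stored on the clustering; rebuild approximate
# coordinates from centroids so relabeling can recompute exact centroids
#' @noRd
centroid_coords <- function(clustering) {
  if (is.null(clustering$centroids)) return(NULL)
  coords <- clustering$centroids[clustering$assignment, , drop = FALSE]
  coords[is.na(clustering$assignment), ] <- NA_real_
  rownames(coords) <- names(clustering$assignment)
  coords
}
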