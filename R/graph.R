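#' Scale a 2D embedding to a target coordinate half-range
#'
#' Multiplies all coordinates by a single global factor so that the largest
#' absolute coordinate (over both axes) equals `half_range`; the aspect ratio
#' and all distance ratios are preserved. Graph construction operates on the
#' scaled coordinates, so the edge `cutoff` is interpreted in scaled units.
#'
#' @param emb n x 2 coordinate matrix (or data frame with cell id, x, y).
#' @param half_range Positive target half-range, or `"auto"`: 200 for up to
#'   8000 cells, 400 beyond (the ranges recommended for tSNE outputs of a few
#'   thousand vs. ~16k cells). For small simulated datasets a smaller value
#'   keeps the expected nearest-neighbour spacing below the edge cutoff; see
#'   the methods vignette.
#' @return The scaled embedding matrix.
#' @examples
#' emb <- cbind(x = runif(100, -50, 50), y = runif(100, -50, 50))
#' range(scale_embedding(emb, 200))
#' @export
scale_embedding <- function(emb, half_range = "auto") {
  emb <- as_embedding(emb)
  if (nrow(emb) < 2L) stop_invalid("need at least 2 cells to scale an embedding")
  if (identical(half_range, "auto"))
    half_range <- if (nrow(emb) <= 8000L) 200 else 400
  if (!is.numeric(half_range) || length(half_range) != 1L || half_range <= 0)
    stop_invalid("half_range must be a positive number or \"auto\"")
  cur <- max(abs(emb))
  if (cur == 0) stop_invalid("degenerate embedding: all cells coincide at the origin")
  if (stats::var(emb[, 1]) == 0 && stats::var(emb[, 2]) == 0)
    stop_invalid("degenerate embedding: all cells coincident")
  emb * (half_range / cur)
}

# all unordered index pairs at Euclidean distance <= r, via grid buckets of
# side r (only the 3 x 3 neighbourhood of a bucket can contain partners)
#' @noRd
radius_pairs <- function(xy, r) {
  n <- nrow(xy)
  empty <- list(i = integer(0), j = integer(0), d = numeric(0))
  if (r <= 0 || n < 2L) return(empty)
  gx <- floor(xy[, 1] / r); gy <- floor(xy[, 2] / r)
  key <- paste(gx, gy, sep = ",")
  bins <- split(seq_len(n), key)
  bin_at <- function(kx, ky) bins[[paste(kx, ky, sep = ",")]]
  # offsets covering each neighbouring bucket pair exactly once
  offs <- list(c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))
  ii <- jj <- list(); dd <- list(); out <- 0L
  push <- function(i, j, d) {
    out <<- out + 1L; ii[[out]] <<- i; jj[[out]] <<- j; dd[[out]] <<- d
  }
  for (b in seq_along(bins)) {
    idx <- bins[[b]]
    kx <- gx[idx[1]]; ky <- gy[idx[1]]
    if (length(idx) > 1L) {               # within-bucket pairs
      D <- cross_dist2(xy[idx, , drop = FALSE], xy[idx, , drop = FALSE])
      sel <- which(upper.tri(D) & D <= r, arr.ind = TRUE)
      if (nrow(sel)) push(idx[sel[, 1]], idx[sel[, 2]], D[sel])
    }
    for (o in offs) {                     # cross-bucket pairs
      nb <- bin_at(kx + o[1], ky + o[2])
      if (is.null(nb)) next
      D <- cross_dist2(xy[idx, , drop = FALSE], xy[nb, , drop = FALSE])
      sel <- which(D <= r, arr.ind = TRUE)
      if (nrow(sel)) push(idx[sel[, 1]], nb[sel[, 2]], D[sel])
    }
  }
  if (out == 0L) return(empty)
  i <- unlist(ii); j <- unlist(jj)
  swap <- i > j
  list(i = ifelse(swap, j, i), j = ifelse(swap, i, j), d = unlist(dd))
}

#' Build a weighted cell graph from a scaled 2D embedding
#'
#' Connects every pair of cells whose Euclidean distance in the (scaled)
#' embedding is at most `cutoff`. Modularity-based community detection treats
#' edge weight as affinity, so by default the stored weight is the inverted
#' distance `cutoff - d + 1e-6` (closer cells weigh more); `"raw-distance"`
#' and `"unweighted"` modes are available for fidelity experiments.
#'
#' @param emb Scaled n x 2 embedding (see [scale_embedding()]).
#' @param cutoff Maximum edge distance (default 3, in scaled units).
#' @param mode Edge weighting: `"inverted-distance"` (default),
#'   `"unweighted"`, or `"raw-distance"`.
#' @return An object of class `cell_graph`: list with the `igraph` object
#'   (`graph`, edge attributes `distance` and `weight`), `coords`, `ids`,
#'   `cutoff`, `mode`, component `membership` and counts.
#' @examples
#' emb <- cbind(x = c(0, 2, 7), y = c(0, 0, 0))
#' g <- build_cell_graph(emb, cutoff = 3)
#' igraph::ecount(g$graph)  # one edge: cells 1-2
#' @export
build_cell_graph <- function(emb, cutoff = 3,
                             mode = c("inverted-distance", "unweighted",
                                      "raw-distance")) {
  emb <- as_embedding(emb)
  mode <- match.arg(mode)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0)
    stop_invalid("cutoff must be a nonnegative number")
  n <- nrow(emb)
  pr <- radius_pairs(emb, cutoff)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- rownames(emb)
  if (length(pr$i)) {
    eps <- 1e-6
    w <- switch(mode,
      "inverted-distance" = cutoff - pr$d + eps,
      "unweighted" = rep(1, length(pr$d)),
      "raw-distance" = pmax(pr$d, eps))
    g <- igraph::add_edges(g, rbind(pr$i, pr$j),
                           attr = list(distance = pr$d, weight = w))
  } else {
    warning("cell graph has no edges (cutoff ", cutoff,
            " below all pairwise distances)")
  }
  comp <- igraph::components(g)
  iso <- sum(igraph::degree(g) == 0)
  if (iso > 0)
    message(iso, " isolated cell(s) (no neighbour within cutoff ", cutoff, ")")
  structure(list(graph = g, coords = emb, ids = rownames(emb),
                 cutoff = cutoff, mode = mode,
                 membership = comp$membership, n_components = comp$no,
                 n_edges = igraph::ecount(g), n_isolated = iso),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("Cell graph: %d cells, %d edges (cutoff %g, %s weights)\n",
              length(x$ids), x$n_edges, x$cutoff, x$mode))
  cat(sprintf("  %d connected component(s), %d isolated cell(s)\n",
              x$n_components, x$n_isolated))
  invisible(x)
}

#' Over-segment a cell graph with Louvain community detection
#'
#' Runs modularity-based Louvain community detection on the weighted cell
#' graph, escalating the resolution parameter geometrically (x1.5, at most
#' `max_rounds` rounds) until the community count N exceeds the requested
#' `k`. The subsequent greedy merge step ([merge_to_k()]) reduces the N
#' communities to exactly k. Connected components are handled independently
#' by Louvain itself (communities never span components).
#'
#' @param cg A [build_cell_graph()] result.
#' @param k Target cluster count that N must exceed.
#' @param resolution Starting Louvain resolution (default 1).
#' @param max_rounds Escalation cap (default 20).
#' @param seed Optional RNG seed for reproducible community detection.
#' @return A `cell_clustering` (see [partition()]) with `N > k` clusters;
#'   attributes `resolution` (final value) and `N`.
#' @export
louvain_oversegment <- function(cg, k, resolution = 1, max_rounds = 20L,
                                seed = NULL) {
  stopifnot(inherits(cg, "cell_graph"))
  n <- length(cg$ids)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_invalid("k must be a positive integer")
  if (k >= n)
    stop_invalid("cannot over-segment to more than k = ", k,
                 " communities with only ", n, " cells")
  with_seed(seed, {
    res <- resolution
    memb <- NULL; N <- 0L
    for (round in seq_len(max_rounds)) {
      if (cg$n_edges == 0L) {
        memb <- seq_len(n)   # edgeless graph: singleton communities
      } else {
        cl <- igraph::cluster_louvain(cg$graph, resolution = res)
        memb <- as.integer(igraph::membership(cl))
      }
      N <- length(unique(memb))
      if (N > k) break
      res <- res * 1.5
    }
    if (N <= k)
      stop_invalid("over-segmentation failure: reached N = ", N,
                   " communities for k = ", k, " with ", n,
                   " cells after ", max_rounds, " resolution escalations")
    out <- new_clustering(memb, cg$coords)
    attr(out, "resolution") <- res
    attr(out, "N") <- N
    out
  })
}
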