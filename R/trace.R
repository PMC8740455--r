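# Cluster evolution tracing across a series of k values.

#' Build a cluster evolution tree from a series of clusterings
#'
#' Links clusters at consecutive k levels: the parent of a cluster at the
#' larger k is the smaller-k cluster holding the maximal number of its cells
#' (ties broken by the smaller parent label). For a nested series (one merge
#' path, see [partition_series()]) every child is a subset of its parent and
#' the edge overlap equals the child size.
#'
#' @param series A `cluster_series`, or a list of `cell_clustering` objects
#'   covering the same cells (ordered or orderable by ascending k).
#' @return Object of class `evolution_tree`: list with `levels` (k values),
#'   `nodes` (data frame: id, level, k, cluster, size) and `edges` (data
#'   frame: parent, child, overlap).
#' @export
build_tree <- function(series) {
  cls <- if (inherits(series, "cluster_series")) unclass(series)$clusterings
         else series
  if (!length(cls)) stop_invalid("empty series")
  if (!all(vapply(cls, inherits, logical(1), "cell_clustering")))
    stop_invalid("series must contain cell_clustering objects")
  ks <- unname(vapply(cls, function(cl) cl$k, integer(1)))
  cls <- cls[order(ks)]
  ks <- sort(ks)
  ## assigned cell sets must agree across levels
  cells <- lapply(cls, function(cl) sort(names(cl$assignment)[!is.na(cl$assignment)]))
  for (i in seq_along(cells)[-1]) {
    if (!identical(cells[[i]], cells[[1]]))
      stop_invalid("inconsistent cell sets between series levels (k = ",
                   ks[1], " vs k = ", ks[i], ")")
  }
  nodes <- do.call(rbind, lapply(seq_along(cls), function(i) {
    cl <- cls[[i]]
    data.frame(id = sprintf("k%d_c%d", ks[i], seq_len(cl$k)),
               level = i, k = ks[i], cluster = seq_len(cl$k),
               size = cl$sizes)
  }))
  edges <- NULL
  if (length(cls) > 1L) {
    edges <- do.call(rbind, lapply(seq_along(cls)[-1], function(i) {
      pa <- cls[[i - 1]]$assignment
      ch <- cls[[i]]$assignment
      ch <- ch[names(pa)]                      # align by cell id
      keep <- !is.na(pa) & !is.na(ch)
      ov <- table(parent = factor(pa[keep], levels = sort(unique(pa[keep]))),
                  child = factor(ch[keep], levels = sort(unique(ch[keep]))))
      parent_of <- apply(ov, 2, which.max)     # first max: smaller label
      overlap <- ov[cbind(parent_of, seq_len(ncol(ov)))]
      data.frame(parent = sprintf("k%d_c%d", ks[i - 1],
                                  as.integer(rownames(ov))[parent_of]),
                 child = sprintf("k%d_c%d", ks[i],
                                 as.integer(colnames(ov))),
                 overlap = as.integer(overlap))
    }))
  }
  structure(list(levels = ks, nodes = nodes, edges = edges),
            class = "evolution_tree")
}

#' @export
print.evolution_tree <- function(x, ...) {
  cat(sprintf("Cluster evolution tree: %d level(s) (k = %s), %d nodes, %d edges\n",
              length(x$levels), paste(x$levels, collapse = ", "),
              nrow(x$nodes), if (is.null(x$edges)) 0L else nrow(x$edges)))
  invisible(x)
}

# deterministic depth-first ordering of nodes: roots and children by label
#' @noRd
tree_children <- function(tree) {
  if (is.null(tree$edges)) return(list())
  split(tree$edges$child, factor(tree$edges$parent, levels = tree$nodes$id))
}

#' Ladder layout for an evolution tree
#'
#' Rows correspond to levels (smallest k on top); horizontal slots are
#' assigned depth-first so that children sit grouped beneath their parent,
#' which takes the mean x of its children. Dot radius scales with the square
#' root of cluster size (`radius = 0.45 * sqrt(size / max_size)` slot units),
#' so plotted dot area is proportional to cell count.
#'
#' @param tree An [build_tree()] result.
#' @return List with `nodes` (id, level, k, cluster, size, x, y, radius) and
#'   `edges` (parent, child, overlap, x0, y0, x1, y1); both deterministic
#'   for a given tree.
#' @export
layout_ladder <- function(tree) {
  stopifnot(inherits(tree, "evolution_tree"))
  nodes <- tree$nodes
  kids <- tree_children(tree)
  x <- setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  slot <- 0
  assign_x <- function(id) {
    ch <- kids[[id]]
    if (is.null(ch) || !length(ch)) {
      slot <<- slot + 1
      x[id] <<- slot
    } else {
      for (c in sort(ch)) assign_x(c)
      x[id] <<- mean(x[ch])
    }
    invisible(NULL)
  }
  roots <- nodes$id[nodes$level == 1L]
  for (r in roots) assign_x(r)
  out <- nodes
  out$x <- unname(x[out$id])
  out$y <- -out$level                      # top row = smallest k
  out$radius <- 0.45 * sqrt(out$size / max(out$size))
  edges <- tree$edges
  if (!is.null(edges)) {
    edges$x0 <- out$x[match(edges$parent, out$id)]
    edges$y0 <- out$y[match(edges$parent, out$id)]
    edges$x1 <- out$x[match(edges$child, out$id)]
    edges$y1 <- out$y[match(edges$child, out$id)]
  }
  list(nodes = out, edges = edges)
}

#' Circular layout for an evolution tree
#'
#' Levels map to concentric rings (smallest k innermost). Each root receives
#' an angular span proportional to its cell count (spans on the inner ring
#' sum to 360 degrees exactly); children subdivide their parent's span in
#' proportion to their sizes, so each child's span lies within its parent's.
#'
#' @param tree An [build_tree()] result.
#' @return List with `nodes` (id, level, k, cluster, size, ring, angle,
#'   span, x, y, radius) - `angle`/`span` in degrees - and `edges` with
#'   endpoint coordinates.
#' @export
layout_circle <- function(tree) {
  stopifnot(inherits(tree, "evolution_tree"))
  nodes <- tree$nodes
  kids <- tree_children(tree)
  start <- setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  span <- setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  assign_span <- function(id, a0, a1) {
    start[id] <<- a0; span[id] <<- a1 - a0
    ch <- sort(kids[[id]])
    if (length(ch)) {
      w <- nodes$size[match(ch, nodes$id)]
      bounds <- a0 + (a1 - a0) * cumsum(c(0, w)) / sum(w)
      for (i in seq_along(ch)) assign_span(ch[i], bounds[i], bounds[i + 1])
    }
    invisible(NULL)
  }
  roots <- nodes$id[nodes$level == 1L]
  rw <- nodes$size[match(roots, nodes$id)]
  rb <- 360 * cumsum(c(0, rw)) / sum(rw)
  for (i in seq_along(roots)) assign_span(roots[i], rb[i], rb[i + 1])
  out <- nodes
  out$ring <- out$level
  out$angle <- unname(start[out$id] + span[out$id] / 2)
  out$span <- unname(span[out$id])
  theta <- out$angle * pi / 180
  out$x <- out$ring * cos(theta)
  out$y <- out$ring * sin(theta)
  out$radius <- 0.45 * sqrt(out$size / max(out$size))
  edges <- tree$edges
  if (!is.null(edges)) {
    edges$x0 <- out$x[match(edges$parent, out$id)]
    edges$y0 <- out$y[match(edges$parent, out$id)]
    edges$x1 <- out$x[match(edges$child, out$id)]
    edges$y1 <- out$y[match(edges$child, out$id)]
  }
  list(nodes = out, edges = edges)
}

#' @param x An `evolution_tree`.
#' @param type `"ladder"` or `"circle"`.
#' @param ... Passed to [graphics::plot()].
#' @rdname build_tree
#' @export
plot.evolution_tree <- function(x, type = c("ladder", "circle"), ...) {
  type <- match.arg(type)
  lay <- if (type == "ladder") layout_ladder(x) else layout_circle(x)
  nd <- lay$nodes
  graphics::plot(nd$x, nd$y, type = "n", xlab = "", ylab = "", axes = FALSE, ...)
  if (!is.null(lay$edges))
    graphics::segments(lay$edges$x0, lay$edges$y0, lay$edges$x1, lay$edges$y1,
                       col = "grey60")
  graphics::symbols(nd$x, nd$y, circles = nd$radius, inches = FALSE,
                    add = TRUE, bg = "steelblue", fg = "grey30")
  invisible(lay)
}
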