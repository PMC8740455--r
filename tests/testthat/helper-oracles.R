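# Independent oracles used to cross-check the package implementations.
# These deliberately use the simplest possible algorithm (brute force,
# rescan-everything greedy, hand-rolled step-up) rather than sharing code
# with the package.

# all-pairs distance-threshold edge set (i < j), O(n^2)
oracle_edges <- function(coords, cutoff) {
  D <- as.matrix(dist(coords))
  sel <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
  data.frame(i = sel[, 1], j = sel[, 2], d = D[sel])
}

# greedy merge-to-k that rescans all centroid distances at every step;
# adjacency = any graph edge between member cells, recomputed from scratch
oracle_greedy_merge <- function(assignment, coords, edges, k) {
  clusters <- unname(split(seq_along(assignment), assignment))
  adjacent <- function(a, b) {
    any((edges$i %in% a & edges$j %in% b) | (edges$i %in% b & edges$j %in% a))
  }
  while (length(clusters) > k) {
    cent <- t(vapply(clusters, function(m) colMeans(coords[m, , drop = FALSE]),
                     numeric(2)))
    n <- length(clusters)
    best <- NULL; best_d <- Inf; best_adj <- FALSE
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      d <- sqrt(sum((cent[a, ] - cent[b, ])^2))
      adj <- adjacent(clusters[[a]], clusters[[b]])
      better <- if (adj == best_adj) d < best_d else adj > best_adj
      if (better) { best <- c(a, b); best_d <- d; best_adj <- adj }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  clusters
}

# canonical set-of-sets representation of a partition for equality checks
partition_sets <- function(x) {
  cl <- if (inherits(x, "cell_clustering")) {
    split(seq_along(x$assignment), x$assignment)
  } else x
  unname(lapply(cl, sort))[order(vapply(lapply(cl, sort), `[`, numeric(1), 1))]
}

# Benjamini-Hochberg step-up written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# AUC via the rank-sum (Mann-Whitney) statistic with midranks for ties
oracle_auc <- function(positive, scores) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small well-separated blob embedding with known blob labels
blob_embedding <- function(n_per_blob, centers, sd = 1, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    n_blob <- nrow(centers)
    lab <- rep(seq_len(n_blob), each = n_per_blob)
    emb <- centers[lab, , drop = FALSE] +
      matrix(rnorm(2 * n_per_blob * n_blob, sd = sd), ncol = 2)
    rownames(emb) <- sprintf("c%03d", seq_len(nrow(emb)))
    colnames(emb) <- c("x", "y")
    list(emb = emb, labels = lab)
  })
}

# tiny expression matrix with named genes/cells
tiny_expr <- function(values, n_genes, n_cells) {
  m <- matrix(values, nrow = n_genes, ncol = n_cells)
  dimnames(m) <- list(sprintf("g%d", seq_len(n_genes)),
                      sprintf("c%d", seq_len(n_cells)))
  m
}
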