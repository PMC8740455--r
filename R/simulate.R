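#' Simulation configuration for dropout-structured scRNA-seq data
#'
#' Bundles the parameters of the synthetic-data generator: matrix dimensions,
#' the per-entry dropout (observed-zero) probability, ground-truth latent
#' gene-pair correlations, and the cell-population layout used for the 2D
#' embedding blobs.
#'
#' @param n_genes,n_cells Positive integers; matrix dimensions.
#' @param zero_prob Probability in `[0, 1]` that any observed entry is zeroed
#'   by dropout (default 0.95, the rate typical of 10x PBMC data).
#' @param latent_pairs `NULL`, or a data frame / 3-column matrix with columns
#'   `gene_a`, `gene_b` (integer gene indices) and `rho` (latent log-scale
#'   correlation in `[-1, 1]`).
#' @param n_types Number of cell populations (embedding blobs), `>= 1`.
#' @param type_separation Spacing between adjacent blob centroids, in
#'   embedding units (default 20, comfortably larger than `blob_sd`).
#' @param blob_sd Within-blob standard deviation of cell coordinates
#'   (default 2 embedding units).
#' @param n_marker_genes Number of marker genes *per type* whose latent
#'   log-expression is shifted by `marker_shift` in that type (default 0).
#' @param marker_shift Log-scale mean shift of marker genes (default 1).
#' @param dropout_mode `"independent"` (entry-wise Bernoulli, the default) or
#'   `"expression"` (zero probability decreasing logistically in the latent
#'   log-expression; `zero_prob` then sets the rate at the latent mean).
#' @param dropout_slope Slope of the logistic dropout curve when
#'   `dropout_mode = "expression"` (default 1).
#' @param seed Integer RNG seed recorded in the configuration; all generator
#'   randomness flows from it.
#' @return An object of class `sim_config`.
#' @seealso [simulate_dataset()], [run_merge_simulation()]
#' @export
sim_config <- function(n_genes, n_cells, zero_prob = 0.95, latent_pairs = NULL,
                       n_types = 1L, type_separation = 20, blob_sd = 2,
                       n_marker_genes = 0L, marker_shift = 1,
                       dropout_mode = c("independent", "expression"),
                       dropout_slope = 1, seed = 1L) {
  n_genes <- as.integer(n_genes); n_cells <- as.integer(n_cells)
  if (is.na(n_genes) || n_genes < 1L) stop_invalid("n_genes must be a positive integer")
  if (is.na(n_cells) || n_cells < 1L) stop_invalid("n_cells must be a positive integer")
  if (!is.numeric(zero_prob) || length(zero_prob) != 1L ||
      is.na(zero_prob) || zero_prob < 0 || zero_prob > 1)
    stop_invalid("zero_prob must be in [0, 1]")
  if (!is.null(latent_pairs)) {
    latent_pairs <- as.data.frame(latent_pairs)
    if (ncol(latent_pairs) < 3L) stop_invalid("latent_pairs needs columns gene_a, gene_b, rho")
    names(latent_pairs)[1:3] <- c("gene_a", "gene_b", "rho")
    latent_pairs$gene_a <- as.integer(latent_pairs$gene_a)
    latent_pairs$gene_b <- as.integer(latent_pairs$gene_b)
    with_range <- function(i) !is.na(i) & i >= 1L & i <= n_genes
    if (!all(with_range(latent_pairs$gene_a)) || !all(with_range(latent_pairs$gene_b)))
      stop_invalid("latent_pairs gene indices must lie in 1..n_genes")
    if (any(latent_pairs$gene_a == latent_pairs$gene_b))
      stop_invalid("latent_pairs must pair two distinct genes")
    if (any(abs(latent_pairs$rho) > 1) || any(is.na(latent_pairs$rho)))
      stop_invalid("latent_pairs rho must lie in [-1, 1]")
  }
  n_types <- as.integer(n_types)
  if (is.na(n_types) || n_types < 1L) stop_invalid("n_types must be >= 1")
  if (!is.numeric(type_separation) || type_separation < 0)
    stop_invalid("type_separation must be nonnegative")
  dropout_mode <- match.arg(dropout_mode)
  structure(list(
    n_genes = n_genes, n_cells = n_cells, zero_prob = zero_prob,
    latent_pairs = latent_pairs, n_types = n_types,
    type_separation = type_separation, blob_sd = blob_sd,
    n_marker_genes = as.integer(n_marker_genes), marker_shift = marker_shift,
    dropout_mode = dropout_mode, dropout_slope = dropout_slope,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d genes x %d cells, P(zero) = %g, %d type(s)\n",
              x$n_genes, x$n_cells, x$zero_prob, x$n_types))
  np <- if (is.null(x$latent_pairs)) 0L else nrow(x$latent_pairs)
  cat(sprintf("  latent pairs: %d; markers/type: %d; dropout: %s; seed: %d\n",
              np, x$n_marker_genes, x$dropout_mode, x$seed))
  invisible(x)
}

#' Expected zero fraction after merging m cells
#'
#' Closed form for the probability that a gene's merged (summed or averaged)
#' value over `m` cells is exactly zero when each cell's value is zero
#' independently with probability `p`: `p^m`. This is the analytic reference
#' curve for [run_merge_simulation()].
#'
#' @param p Per-cell zero probability in `[0, 1]`.
#' @param m Number of merged cells (positive integer; vectorized).
#' @return `p^m`, in `[0, 1]`.
#' @examples
#' expected_merged_zero_fraction(0.95, c(1, 2, 10, 50))
#' @export
expected_merged_zero_fraction <- function(p, m) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_invalid("p must be a probability in [0, 1]")
  m <- as.numeric(m)
  if (length(m) < 1L || any(is.na(m)) || any(m < 1) || any(m != floor(m)))
    stop_invalid("m must be a positive integer")
  p^m
}

#' Merged-cell zero-fraction simulation
#'
#' Draws independent Bernoulli zero masks at rate `zero_prob` for
#' `n_genes x n_cells` entries, then, for each merge size `m`, repeatedly
#' samples `m` random cells and records the fraction of genes whose merged
#' value (sum across the `m` cells) is exactly zero. The mean fraction decays
#' as `zero_prob^m` (see [expected_merged_zero_fraction()]), which is the
#' mechanism that cluster averaging exploits.
#'
#' @param config A [sim_config()]; only `n_genes`, `n_cells`, `zero_prob` and
#'   `seed` are used.
#' @param max_m Largest merge size (default 200).
#' @param reps Random cell subsets drawn per merge size (default 1000).
#' @param ms Optional explicit vector of merge sizes; defaults to
#'   `1:max_m`.
#' @return A data frame with one row per merge size: `m`, empirical mean
#'   `zero_fraction`, its standard error `se` across the `reps` draws, and
#'   the closed-form `expected` value.
#' @examples
#' cfg <- sim_config(n_genes = 500, n_cells = 200, zero_prob = 0.9, seed = 1)
#' run_merge_simulation(cfg, reps = 50, ms = c(1, 5, 20))
#' @export
run_merge_simulation <- function(config, max_m = 200L, reps = 1000L, ms = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(ms)) ms <- seq_len(max_m)
  ms <- as.integer(ms)
  if (any(ms < 1L)) stop_invalid("merge sizes must be positive")
  if (max(ms) > config$n_cells)
    stop_invalid("largest merge size exceeds n_cells (", config$n_cells, ")")
  reps <- as.integer(reps)
  if (reps < 1L) stop_invalid("reps must be >= 1")
  p <- config$zero_prob
  with_seed(config$seed, {
    mask <- matrix(runif(config$n_genes * config$n_cells) < p,
                   nrow = config$n_genes)
    res <- lapply(ms, function(m) {
      fr <- vapply(seq_len(reps), function(r) {
        cols <- sample.int(config$n_cells, m)
        mean(rowSums(mask[, cols, drop = FALSE]) == m)
      }, numeric(1))
      c(mean = mean(fr), se = stats::sd(fr) / sqrt(reps))
    })
    res <- do.call(rbind, res)
    data.frame(m = ms, zero_fraction = res[, "mean"], se = res[, "se"],
               expected = p^ms)
  })
}

#' Generate a synthetic zero-inflated scRNA-seq dataset with known truth
#'
#' Latent log-expression is multivariate normal with unit variance per gene;
#' each connected component of the `latent_pairs` graph gets the requested
#' correlation matrix (an error names the offending pairs if it is not
#' positive semi-definite). The leading factor of each component is carried
#' by a per-cell state that varies linearly across the embedding (random
#' direction), so that co-expression varies smoothly between neighbourhoods
#' of transcriptomically similar cells - the structure a tSNE of real data
#' exhibits, and the reason within-cluster averaging denoises rather than
#' merely subsamples. Remaining factors are per-cell noise; the marginal
#' per-cell log-scale correlation of each pair still equals its `rho`.
#' Observed expression is `exp(latent)` with entries independently zeroed at
#' rate `zero_prob` (or expression-dependently, see [sim_config()]).
#'
#' @param config A [sim_config()].
#' @return An object of class `sc_sim`: list with `expression` (sparse
#'   genes x cells dgCMatrix, zero-inflated), `latent` (dense pre-dropout
#'   matrix), `embedding` (n_cells x 2 matrix), `cell_labels` (named
#'   character vector), `marker_genes` (list per type) and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(50, 100, zero_prob = 0.8,
#'   latent_pairs = data.frame(gene_a = 1, gene_b = 2, rho = 0.8), seed = 7))
#' Matrix::nnzero(sim$expression) / length(sim$expression)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes; nc <- config$n_cells
  with_seed(config$seed, {
    gene_ids <- sprintf("g%0*d", nchar(ng), seq_len(ng))
    cell_ids <- sprintf("c%0*d", nchar(nc), seq_len(nc))

    ## cell types and Gaussian-blob embedding
    type_of <- rep(seq_len(config$n_types), length.out = nc)
    type_of <- sort(type_of)
    labels <- paste0("type", type_of)
    centroids <- blob_centroids(config$n_types, config$type_separation)
    emb <- centroids[type_of, , drop = FALSE] +
      matrix(rnorm(2 * nc, sd = config$blob_sd), ncol = 2)
    dimnames(emb) <- list(cell_ids, c("x", "y"))

    ## latent log-expression
    Z <- matrix(rnorm(ng * nc), nrow = ng)
    if (!is.null(config$latent_pairs) && nrow(config$latent_pairs)) {
      Z <- inject_pair_structure(Z, config$latent_pairs, emb)
    }
    if (config$n_marker_genes > 0L) {
      marker_genes <- marker_allocation(config, gene_ids)
      for (t in seq_len(config$n_types)) {
        idx <- match(marker_genes[[t]], gene_ids)
        Z[idx, type_of == t] <- Z[idx, type_of == t] + config$marker_shift
      }
    } else {
      marker_genes <- NULL
    }

    latent <- exp(Z)
    dimnames(latent) <- list(gene_ids, cell_ids)

    ## dropout mask
    p <- config$zero_prob
    if (config$dropout_mode == "independent") {
      mask <- matrix(runif(ng * nc) < p, nrow = ng)
    } else {
      pz <- stats::plogis(stats::qlogis(min(max(p, 1e-12), 1 - 1e-12)) -
                          config$dropout_slope * Z)
      mask <- matrix(runif(ng * nc) < pz, nrow = ng)
    }
    observed <- latent
    observed[mask] <- 0
    observed <- methods::as(methods::as(Matrix::Matrix(observed, sparse = TRUE),
                                        "generalMatrix"), "CsparseMatrix")

    structure(list(
      expression = observed, latent = latent, embedding = emb,
      cell_labels = setNames(labels, cell_ids),
      marker_genes = marker_genes, config = config
    ), class = "sc_sim")
  })
}

#' @export
print.sc_sim <- function(x, ...) {
  zf <- 1 - Matrix::nnzero(x$expression) / length(x$expression)
  cat(sprintf("Synthetic scRNA-seq dataset: %d genes x %d cells (%.1f%% zeros observed)\n",
              nrow(x$expression), ncol(x$expression), 100 * zf))
  cat(sprintf("  %d cell type(s); dropout mode: %s; seed %d\n",
              x$config$n_types, x$config$dropout_mode, x$config$seed))
  invisible(x)
}

# equally spaced blob centroids: adjacent spacing = `sep`
#' @noRd
blob_centroids <- function(n_types, sep) {
  if (n_types == 1L) return(matrix(0, 1, 2))
  if (n_types == 2L) {
    return(rbind(c(-sep / 2, 0), c(sep / 2, 0)))
  }
  radius <- sep / (2 * sin(pi / n_types))
  theta <- 2 * pi * (seq_len(n_types) - 1) / n_types
  cbind(radius * cos(theta), radius * sin(theta))
}

# first genes not involved in latent pairs become type markers, round-robin
#' @noRd
marker_allocation <- function(config, gene_ids) {
  used <- if (is.null(config$latent_pairs)) integer(0) else
    unique(c(config$latent_pairs$gene_a, config$latent_pairs$gene_b))
  free <- setdiff(seq_len(config$n_genes), used)
  need <- config$n_marker_genes * config$n_types
  if (length(free) < need)
    stop_invalid("not enough genes free of latent pairs for ", need, " markers")
  take <- free[seq_len(need)]
  split(gene_ids[take], rep(seq_len(config$n_types), each = config$n_marker_genes))
}

# overwrite rows of Z belonging to correlated components with factor draws;
# leading factor of each component is a standardized linear field over the
# embedding so that the shared signal varies between spatial neighbourhoods
#' @noRd
inject_pair_structure <- function(Z, pairs, emb) {
  nc <- ncol(Z)
  g <- igraph::graph_from_edgelist(cbind(pairs$gene_a, pairs$gene_b),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  genes_in_pairs <- which(comp > 0 & igraph::degree(g) > 0)
  for (cid in unique(comp[genes_in_pairs])) {
    genes <- intersect(which(comp == cid), genes_in_pairs)
    m <- length(genes)
    C <- diag(m)
    rows <- which(pairs$gene_a %in% genes | pairs$gene_b %in% genes)
    for (r in rows) {
      i <- match(pairs$gene_a[r], genes); j <- match(pairs$gene_b[r], genes)
      C[i, j] <- C[j, i] <- pairs$rho[r]
    }
    eg <- eigen(C, symmetric = TRUE)
    if (min(eg$values) < -1e-8) {
      bad <- paste(sprintf("(%d,%d,rho=%g)", pairs$gene_a[rows],
                           pairs$gene_b[rows], pairs$rho[rows]), collapse = " ")
      stop_invalid("latent_pairs correlation matrix is not positive ",
                   "semi-definite for pairs ", bad)
    }
    A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), m)
    theta <- runif(1, 0, 2 * pi)
    u <- cos(theta) * emb[, 1] + sin(theta) * emb[, 2]
    su <- stats::sd(u)
    u <- if (su > 0) (u - mean(u)) / su else rnorm(nc)
    factors <- rbind(u, if (m > 1) matrix(rnorm((m - 1) * nc), nrow = m - 1))
    Z[genes, ] <- A %*% factors
  }
  Z
}

#' Per-gene and per-cell zero fractions
#'
#' The two marginal views of dropout abundance: the fraction of cells in
#' which each gene is zero, and the fraction of genes that are zero in each
#' cell.
#'
#' @param expr Genes x cells expression matrix (dense or sparse).
#' @return List with numeric vectors `gene` (length n_genes) and `cell`
#'   (length n_cells), both in `[0, 1]`.
#' @export
zero_diagnostics <- function(expr) {
  expr <- validate_expression(expr)
  if (is(expr, "sparseMatrix")) {
    ind <- expr
    ind@x <- as.double(ind@x != 0)
    nz_gene <- Matrix::rowSums(ind)
    nz_cell <- Matrix::colSums(ind)
  } else {
    nz_gene <- rowSums(expr != 0)
    nz_cell <- colSums(expr != 0)
  }
  list(gene = setNames(1 - nz_gene / ncol(expr), rownames(expr)),
       cell = setNames(1 - nz_cell / nrow(expr), colnames(expr)))
}
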