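# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded operations do not
#' perturb the global random stream. A NULL seed evaluates the code as-is.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' @noRd
stop_invalid <- function(...) stop(..., call. = FALSE)

#' Validate and canonicalize a genes x cells expression matrix
#'
#' Accepts a base matrix or any Matrix sparse/dense matrix; requires unique
#' rownames (genes) and colnames (cells), finite nonnegative values.
#' @noRd
validate_expression <- function(expr) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!(is.matrix(expr) || is(expr, "Matrix")))
    stop_invalid("expression must be a matrix (genes x cells)")
  if (nrow(expr) < 1L || ncol(expr) < 1L)
    stop_invalid("expression matrix is empty")
  gn <- rownames(expr); cn <- colnames(expr)
  if (is.null(gn)) gn <- sprintf("g%d", seq_len(nrow(expr)))
  if (is.null(cn)) cn <- sprintf("c%d", seq_len(ncol(expr)))
  if (anyDuplicated(gn)) stop_invalid("duplicate gene ids in expression matrix")
  if (anyDuplicated(cn)) stop_invalid("duplicate cell ids in expression matrix")
  vals <- if (is(expr, "sparseMatrix")) expr@x else as.numeric(expr)
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0)))
    stop_invalid("expression matrix must contain finite nonnegative values")
  dimnames(expr) <- list(gn, cn)
  expr
}

#' Validate / canonicalize a 2D embedding to an n x 2 matrix with cell ids
#' @noRd
as_embedding <- function(emb) {
  if (is.data.frame(emb)) {
    idcol <- which(vapply(emb, is.character, logical(1)) |
                   vapply(emb, is.factor, logical(1)))
    if (length(idcol)) {
      ids <- as.character(emb[[idcol[1]]])
      emb <- as.matrix(emb[, setdiff(seq_along(emb), idcol[1])[1:2], drop = FALSE])
      rownames(emb) <- ids
    } else {
      emb <- as.matrix(emb)
    }
  }
  if (!is.matrix(emb) || ncol(emb) < 2L)
    stop_invalid("embedding must be an n x 2 matrix or data frame (cell, x, y)")
  emb <- emb[, 1:2, drop = FALSE]
  storage.mode(emb) <- "double"
  if (nrow(emb) < 1L) stop_invalid("embedding is empty")
  if (any(!is.finite(emb))) stop_invalid("embedding coordinates must be finite")
  if (is.null(rownames(emb))) rownames(emb) <- sprintf("c%d", seq_len(nrow(emb)))
  if (anyDuplicated(rownames(emb))) stop_invalid("duplicate cell ids in embedding")
  colnames(emb) <- c("x", "y")
  emb
}

#' Euclidean distance between rows of two 2-column matrices
#' @noRd
cross_dist2 <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}
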