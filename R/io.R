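# File readers and writers. Canonical internal orientation is genes x cells;
# TSV is the canonical output dialect (tab-separated, UTF-8, header row).

#' @noRd
guess_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' @noRd
check_readable <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  if (file.size(path) == 0) stop_invalid("empty input file: ", path)
  invisible(path)
}

#' @noRd
read_table_auto <- function(path, header = TRUE) {
  check_readable(path)
  read.delim(path, sep = guess_sep(path), header = header,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read an expression matrix (Matrix-Market sparse or dense CSV/TSV)
#'
#' Sparse input is the 10x-style triplet layout: a `.mtx` file plus one-id-
#' per-line gene and cell label files (1-based indices on disk). Dense input
#' is a CSV/TSV with gene ids in the first column and cell ids in the
#' header. Either orientation on disk is accepted; the returned matrix is
#' always genes x cells.
#'
#' @param path Matrix file (`.mtx`, `.csv` or `.tsv`/`.txt`).
#' @param genes,cells Label file paths (required for `.mtx`; one id per
#'   line, first column used).
#' @param orientation Orientation of the file on disk:
#'   `"genes_by_cells"` (default) or `"cells_by_genes"`.
#' @return A genes x cells `dgCMatrix` with gene/cell ids as dimnames.
#' @export
read_expression <- function(path, genes = NULL, cells = NULL,
                            orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  check_readable(path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes) || is.null(cells))
      stop_invalid("Matrix-Market input needs gene and cell label files")
    m <- Matrix::readMM(path)
    gn <- read.delim(check_readable(genes), header = FALSE,
                     stringsAsFactors = FALSE)[[1]]
    cn <- read.delim(check_readable(cells), header = FALSE,
                     stringsAsFactors = FALSE)[[1]]
    if (orientation == "cells_by_genes") m <- Matrix::t(m)
    if (nrow(m) != length(gn))
      stop_invalid("gene label count (", length(gn),
                   ") does not match matrix rows (", nrow(m), ")")
    if (ncol(m) != length(cn))
      stop_invalid("cell label count (", length(cn),
                   ") does not match matrix columns (", ncol(m), ")")
    dimnames(m) <- list(gn, cn)
    m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  } else {
    df <- read_table_auto(path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    if (orientation == "cells_by_genes") m <- t(m)
    m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  }
  validate_expression(m)
}

#' Write an expression matrix as Matrix-Market triplets plus label files
#'
#' @param expr Genes x cells matrix.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"expression"`).
#' @return Invisibly, the three file paths (matrix, genes, cells).
#' @export
write_expression <- function(expr, dir, prefix = "expression") {
  expr <- validate_expression(expr)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- methods::as(methods::as(Matrix::Matrix(expr, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_genes.tsv", "_cells.tsv")))
  Matrix::writeMM(sp, paths[1])
  writeLines(rownames(expr), paths[2])
  writeLines(colnames(expr), paths[3])
  invisible(paths)
}

#' Read a per-cell 2D embedding (cell id, x, y)
#'
#' @param path CSV/TSV with a header; first column cell id, next two the
#'   coordinates.
#' @param expr Optional expression matrix to align cell order against;
#'   unmatched ids on either side are reported, zero overlap is an error.
#' @return n x 2 coordinate matrix with cell ids as rownames.
#' @export
read_embedding <- function(path, expr = NULL) {
  df <- read_table_auto(path)
  if (ncol(df) < 3L) stop_invalid("embedding file needs columns: cell, x, y")
  emb <- as.matrix(df[, 2:3])
  storage.mode(emb) <- "double"
  rownames(emb) <- as.character(df[[1]])
  emb <- as_embedding(emb)
  if (!is.null(expr)) {
    expr_ids <- colnames(validate_expression(expr))
    common <- intersect(expr_ids, rownames(emb))
    if (!length(common))
      stop_invalid("no embedding cell ids match the expression matrix")
    n_only_expr <- length(setdiff(expr_ids, rownames(emb)))
    n_only_emb <- length(setdiff(rownames(emb), expr_ids))
    if (n_only_expr || n_only_emb)
      message("embedding/expression id mismatch: ", n_only_expr,
              " expression cell(s) without coordinates, ", n_only_emb,
              " embedding row(s) dropped")
    emb <- emb[expr_ids[expr_ids %in% common], , drop = FALSE]
  }
  emb
}

#' Read a two-column gene-pair table
#'
#' @param path TSV/CSV with two gene-id columns; a header row is detected
#'   when its fields start with "gene".
#' @param expr Optional expression matrix; pairs naming unknown genes are
#'   reported (they are skipped later by [correlate_pairs()]).
#' @return Data frame with columns gene_a, gene_b.
#' @export
read_pairs <- function(path, expr = NULL) {
  check_readable(path)
  first <- strsplit(readLines(path, n = 1L), guess_sep(path))[[1]]
  has_header <- length(first) >= 2L && all(grepl("^gene", first[1:2],
                                                 ignore.case = TRUE))
  df <- read.delim(path, sep = guess_sep(path), header = has_header,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_invalid("gene-pair file needs two columns")
  out <- data.frame(gene_a = as.character(df[[1]]),
                    gene_b = as.character(df[[2]]))
  if (!nrow(out)) stop_invalid("gene-pair file contains no pairs")
  if (!is.null(expr)) {
    known <- rownames(validate_expression(expr))
    bad <- !(out$gene_a %in% known) | !(out$gene_b %in% known)
    if (all(bad)) stop_invalid("no pair genes match the expression matrix")
    if (any(bad)) message(sum(bad), " pair(s) reference unknown gene ids")
  }
  out
}

#' Read per-cell type labels (cell id, label)
#'
#' @param path CSV/TSV with a header; first column cell id, second the label.
#' @param expr Optional expression matrix to align against.
#' @return Character vector of labels named by cell id.
#' @export
read_labels <- function(path, expr = NULL) {
  df <- read_table_auto(path)
  if (ncol(df) < 2L) stop_invalid("label file needs columns: cell, label")
  labels <- setNames(as.character(df[[2]]), as.character(df[[1]]))
  if (!is.null(expr)) {
    ids <- colnames(validate_expression(expr))
    if (!any(ids %in% names(labels)))
      stop_invalid("no label cell ids match the expression matrix")
    labels <- labels[ids]
  }
  labels
}

#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster assignment table (cell, cluster)
#' @param clustering A `cell_clustering`.
#' @param path Output TSV path.
#' @export
write_assignment <- function(clustering, path) {
  write_tsv(data.frame(cell = names(clustering$assignment),
                       cluster = clustering$assignment), path)
}

#' Write a cluster summary table (cluster, size, centroid_x, centroid_y)
#' @param clustering A `cell_clustering`.
#' @param path Output TSV path.
#' @export
write_cluster_summary <- function(clustering, path) {
  cent <- clustering$centroids
  if (is.null(cent)) cent <- matrix(NA_real_, clustering$k, 2)
  write_tsv(data.frame(cluster = seq_len(clustering$k),
                       size = clustering$sizes,
                       centroid_x = cent[, 1], centroid_y = cent[, 2]), path)
}

#' Write an embedding (cell, x, y) as TSV
#' @param emb n x 2 coordinate matrix with cell id rownames.
#' @param path Output TSV path.
#' @export
write_embedding <- function(emb, path) {
  emb <- as_embedding(emb)
  write_tsv(data.frame(cell = rownames(emb), x = emb[, 1], y = emb[, 2]), path)
}
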