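# End-to-end file-based pipeline and run configuration.

#' Assemble and validate a pipeline run configuration
#'
#' @param ... Configuration fields (see Details) or a single list.
#' @details Recognized fields: `expression` (path; `.mtx` needs `genes` and
#'   `cells` label paths), `orientation`, `embedding` (path), `pairs`
#'   (optional path), `labels` (optional path), `target` (label for
#'   classification), `k` or `ks`, `cutoff` (3), `scale` (`"auto"`), `mode`
#'   (`"inverted-distance"`), `min_cells` (10), `small_mode` (`"none"`,
#'   `"merge"` or `"drop"`), `alpha` (0.05), `folds` (10), `n_features`
#'   (500), `seed` (required), `outdir` (required).
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args)))
    args <- args[[1]]
  defaults <- list(expression = NULL, genes = NULL, cells = NULL,
                   orientation = "genes_by_cells", embedding = NULL,
                   pairs = NULL, labels = NULL, target = NULL,
                   k = NULL, ks = NULL, cutoff = 3, scale = "auto",
                   mode = "inverted-distance", min_cells = 10L,
                   small_mode = "none", alpha = 0.05, folds = 10L,
                   n_features = 500L, seed = NULL, outdir = NULL)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop_invalid("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, args)
  if (is.null(cfg$expression) || is.null(cfg$embedding))
    stop_invalid("config requires 'expression' and 'embedding' paths")
  if (is.null(cfg$seed)) stop_invalid("config requires a 'seed'")
  if (is.null(cfg$outdir)) stop_invalid("config requires an 'outdir'")
  if (is.null(cfg$k) && is.null(cfg$ks))
    stop_invalid("config requires 'k' or 'ks'")
  if (!cfg$small_mode %in% c("none", "merge", "drop"))
    stop_invalid("small_mode must be none, merge or drop")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Relative paths in the file are resolved against its directory.
#'
#' @param path YAML config path.
#' @param overrides Optional named list overriding file values.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, overrides = NULL) {
  check_readable(path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("expression", "genes", "cells", "embedding", "pairs", "labels")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      cfg[[f]] <- file.path(base, cfg[[f]])
  }
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  run_config(cfg)
}

#' Run the full pipeline from a configuration
#'
#' Reads the inputs, partitions the embedding graph at the configured k (or
#' series of ks), optionally filters undersized clusters, and then - as the
#' supplied inputs permit - computes cluster-level and single-cell gene-pair
#' correlations, cross-validated cell-type classification, and the cluster
#' evolution tree. All result tables are written as TSV into `outdir`
#' together with a machine-readable JSON run report (parameters, input
#' checksums, data summaries). Reruns with the same configuration and seed
#' reproduce the result tables byte for byte.
#'
#' @param config A [run_config()], [read_run_config()] result, or list.
#' @return Invisibly, a list with the in-memory results and the report.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  t0 <- Sys.time()
  expr <- read_expression(config$expression, genes = config$genes,
                          cells = config$cells,
                          orientation = config$orientation)
  emb <- read_embedding(config$embedding, expr = expr)
  if (nrow(emb) != ncol(expr))
    stop_invalid("stage input: embedding covers ", nrow(emb), " of ",
                 ncol(expr), " cells")
  expr <- expr[, rownames(emb), drop = FALSE]
  ks <- sort(unique(as.integer(if (!is.null(config$ks)) config$ks else config$k)))
  if (max(ks) > ncol(expr))
    stop_invalid("pre-flight: k = ", max(ks), " exceeds n_cells = ", ncol(expr))
  pairs <- if (!is.null(config$pairs)) read_pairs(config$pairs, expr = expr)
  labels <- if (!is.null(config$labels)) read_labels(config$labels, expr = expr)
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  outp <- function(...) file.path(config$outdir, sprintf(...))

  series <- partition_series(emb, ks, cutoff = config$cutoff,
                             scale = config$scale, mode = config$mode,
                             seed = config$seed)
  k_main <- max(ks)
  cl_main <- series[[k_main]]
  filtered <- NULL
  if (config$small_mode != "none") {
    cl_main <- filter_small_clusters(cl_main, min_cells = config$min_cells,
                                     mode = config$small_mode)
    filtered <- attr(cl_main, "filtered")
  }
  outputs <- character(0)
  for (k in ks) {
    cl_k <- if (k == k_main) cl_main else series[[k]]
    outputs <- c(outputs,
                 write_assignment(cl_k, outp("assignment_k%d.tsv", k)),
                 write_cluster_summary(cl_k, outp("cluster_summary_k%d.tsv", k)))
  }

  cor_cluster <- cor_cell <- NULL
  if (!is.null(pairs)) {
    prof <- cluster_profile(expr, cl_main)
    cor_cluster <- correlate_pairs(prof, pairs, alpha = config$alpha)
    cor_cell <- correlate_pairs(expr, pairs, alpha = config$alpha)
    outputs <- c(outputs,
                 write_tsv(as.data.frame(cor_cluster), outp("pairs_cluster.tsv")),
                 write_tsv(as.data.frame(cor_cell), outp("pairs_cell.tsv")))
  }

  auc <- NULL
  if (!is.null(labels) && !is.null(config$target)) {
    lp <- labeled_profile(expr, labels, config$target, clustering = cl_main)
    auc <- crossvalidate_auc(lp, folds = config$folds, seed = config$seed,
                             n_features = config$n_features)
    base <- crossvalidate_auc(
      labeled_profile(expr, labels, config$target, clustering = NULL),
      folds = config$folds, seed = config$seed,
      n_features = config$n_features)
    outputs <- c(outputs, write_tsv(
      data.frame(method = c("cluster", "cell"), k = c(cl_main$k, ncol(expr)),
                 auc = c(auc$auc, base$auc)), outp("auc.tsv")))
  }

  tree <- NULL
  if (length(ks) >= 2L) {
    tree <- build_tree(series)
    lay <- layout_ladder(tree)
    outputs <- c(outputs,
                 write_tsv(tree$edges, outp("tree_edges.tsv")),
                 write_tsv(lay$nodes, outp("tree_ladder_nodes.tsv")))
  }

  zf <- zero_diagnostics(expr)
  in_files <- unlist(config[c("expression", "genes", "cells", "embedding",
                              "pairs", "labels")])
  report <- list(
    tool = "partcor", version = as.character(packageVersion("partcor")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = config[c("cutoff", "scale", "mode", "min_cells",
                          "small_mode", "alpha", "folds", "n_features")],
    inputs = lapply(as.list(in_files), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    data = list(n_genes = nrow(expr), n_cells = ncol(expr),
                zero_fraction = mean(zf$gene),
                oversegmentation_N = series$N, ks = ks,
                final_k = cl_main$k,
                clusters_below_min = sum(cl_main$sizes < config$min_cells),
                filtered_clusters = length(filtered)),
    correlation = if (!is.null(cor_cluster)) list(
      pairs_tested = sum(cor_cluster$status == "ok"),
      pairs_degenerate = sum(cor_cluster$status == "degenerate"),
      pairs_missing = sum(cor_cluster$status == "missing"),
      significant_cluster = sum(cor_cluster$significant),
      significant_cell = sum(cor_cell$significant)),
    classification = if (!is.null(auc)) list(auc_cluster = auc$auc),
    outputs = basename(outputs)
  )
  jsonlite::write_json(report, outp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message("pipeline complete: ", length(outputs), " table(s) in ", config$outdir)
  invisible(list(series = series, clustering = cl_main,
                 cor_cluster = cor_cluster, cor_cell = cor_cell,
                 auc = auc, tree = tree, report = report))
}
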