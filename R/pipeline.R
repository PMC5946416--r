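#' Run the full weighted-ensemble clustering pipeline
#'
#' Executes the complete workflow on a UMI count matrix:
#' preprocessing filters, the Gini rare-cell stage (high-Gini gene
#' selection, Jaccard distance, DBSCAN), the Fano common-cell stage
#' (top-Fano genes, PCA, k-means with the gap statistic choosing k unless
#' `k_fano` is given), and the cluster-aware weighted consensus that merges
#' the two partitions. Optionally evaluates against reference labels and
#' computes the composite tSNE.
#'
#' Every random step is seeded deterministically from `seed`, so two runs
#' with identical inputs and parameters produce identical partitions.
#'
#' @param counts Count matrix, genes x cells (see [read_counts()]).
#' @param min_cells_per_gene,min_genes_per_cell Preprocessing filters
#'   (see [filter_counts()]).
#' @param normalize Apply median-of-library-size scaling (off by default).
#' @param gini_p High-Gini selection threshold (see [select_high_gini()]).
#' @param loess_span,outlier_quantile,gini_center Gini normalization
#'   controls (see [normalize_gini()]).
#' @param eps,min_pts DBSCAN parameters (see [dbscan_cluster()]).
#' @param n_fano Number of top Fano-factor genes.
#' @param n_pcs Number of principal components.
#' @param k_fano Number of common clusters; `NULL` chooses k with the gap
#'   statistic.
#' @param gap_k_max,gap_n_refs Gap-statistic controls (see
#'   [choose_k_gap()]).
#' @param mu,s,f Consensus weighting parameters (see [derive_params()]).
#' @param k_final Number of consensus clusters; `NULL` applies
#'   [choose_k_final()].
#' @param n_restarts k-means restarts for the Fano and consensus stages.
#' @param seed Master seed.
#' @param ref_labels Optional reference labels (tibble or named vector);
#'   when given, NMI, ARI and per-type MCC are computed.
#' @param compute_tsne Also compute the composite tSNE coordinates.
#' @param block_size Row-block size for consensus construction.
#' @return An object of class `gf_ensemble`; see [tidy.gf_ensemble()],
#'   [glance.gf_ensemble()], [autoplot.gf_ensemble()].
#' @export
run_ensemble <- function(counts,
                         min_cells_per_gene = 3, min_genes_per_cell = 2000,
                         normalize = FALSE,
                         gini_p = 1e-4, loess_span = 0.9,
                         outlier_quantile = 0.9,
                         gini_center = c("mean", "median"),
                         eps = 0.5, min_pts = 3,
                         n_fano = 1000, n_pcs = 50,
                         k_fano = NULL, gap_k_max = 5, gap_n_refs = 20,
                         mu = 0.05, s = 0.0125, f = 0.025,
                         k_final = NULL, n_restarts = 20, seed = 1L,
                         ref_labels = NULL, compute_tsne = FALSE,
                         block_size = 1024) {
  gini_center <- match.arg(gini_center)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
  }

  validate_counts(counts)
  raw_dim <- dim(counts)
  m <- filter_counts(counts, min_cells_per_gene, min_genes_per_cell)
  if (normalize) m <- normalize_libsize(m)
  tick("preprocess")

  scores <- score_genes(m, span = loess_span,
                        outlier_quantile = outlier_quantile,
                        center = gini_center)
  high_gini <- select_high_gini(scores, p_threshold = gini_p)
  jd <- jaccard_distance(m[high_gini, , drop = FALSE])
  p_gini <- dbscan_cluster(jd, eps = eps, min_pts = min_pts)
  tick("gini_stage")

  top_fano <- select_top_fano(m, n_genes = n_fano)
  emb <- pca_reduce(m[top_fano, , drop = FALSE], n_components = n_pcs)
  gap <- NULL
  if (is.null(k_fano)) {
    kg <- choose_k_gap(emb, k_max = gap_k_max, n_refs = gap_n_refs,
                       seed = seed + 2L)
    k_fano <- as.integer(kg)
    gap <- attr(kg, "gap_table")
  }
  p_fano <- kmeans_cluster(emb, k_fano, n_restarts = n_restarts,
                           seed = seed + 1L)
  tick("fano_stage")

  params <- derive_params(mu = mu, s = s, f = f)
  weights <- cell_weights(p_gini, params)
  if (is.null(k_final)) {
    k_final <- as.integer(choose_k_final(p_gini, p_fano, params))
  }
  mbar <- consensus_matrix(p_gini, p_fano, params, block_size = block_size)
  p_final <- final_cluster(mbar, k_final, n_restarts = n_restarts,
                           seed = seed + 3L)
  tick("consensus")

  metrics <- NULL
  if (!is.null(ref_labels)) {
    ref <- ref_labels_tbl(ref_labels)
    metrics <- list(
      nmi = nmi(p_final, as_partition(ref)),
      ari = ari(p_final, as_partition(ref)),
      mcc_per_type = mcc_per_type(p_final, ref),
      confusion = confusion_map(p_final, ref))
    tick("evaluate")
  }

  tsne <- NULL
  if (compute_tsne) {
    tsne <- composite_tsne(jd, emb, seed = seed + 4L)
    tick("tsne")
  }

  structure(list(
    partition_gini = p_gini,
    partition_fano = p_fano,
    partition_final = p_final,
    k_gini = partition_k(p_gini),
    k_fano = k_fano,
    k_final = k_final,
    scores = scores,
    high_gini_genes = high_gini,
    top_fano_genes = top_fano,
    embedding = emb,
    gini_distance = jd,
    params = params,
    weights = weights,
    gap = gap,
    metrics = metrics,
    tsne = tsne,
    dims = list(raw = raw_dim, filtered = dim(m)),
    options = list(min_cells_per_gene = min_cells_per_gene,
                   min_genes_per_cell = min_genes_per_cell,
                   normalize = normalize, gini_p = gini_p,
                   eps = eps, min_pts = min_pts, n_fano = n_fano,
                   n_pcs = n_pcs, n_restarts = n_restarts, seed = seed),
    timings = timings
  ), class = "gf_ensemble")
}

#' @export
print.gf_ensemble <- function(x, ...) {
  cat("Weighted ensemble clustering\n")
  cat(sprintf("  %d genes x %d cells after filtering (from %d x %d)\n",
              x$dims$filtered[1], x$dims$filtered[2],
              x$dims$raw[1], x$dims$raw[2]))
  cat(sprintf("  rare-cell stage:   %d clusters (DBSCAN, %d high-Gini genes, %d noise cells)\n",
              x$k_gini, length(x$high_gini_genes),
              sum(x$partition_gini$cluster == 0L)))
  cat(sprintf("  common-cell stage: %d clusters (k-means on %d PCs)\n",
              x$k_fano, ncol(x$embedding)))
  cat(sprintf("  consensus:         %d clusters (mu = %g, s = %g, f = %g)\n",
              x$k_final, x$params$mu, x$params$s, x$params$f))
  sizes <- partition_sizes(x$partition_final)
  cat("  consensus cluster sizes:",
      paste(sizes$n_cells[sizes$cluster != 0], collapse = ", "), "\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  vs reference: ARI = %.3f, NMI = %.3f\n",
                x$metrics$ari, x$metrics$nmi))
  }
  invisible(x)
}

#' Tidy a fitted ensemble
#'
#' @param x A `gf_ensemble` object.
#' @param ... Unused.
#' @return One row per cell: `cell_id`, `gini_cluster`, `fano_cluster`,
#'   `cluster` (the consensus assignment), and the cell's consensus weight
#'   `w_tilde_g`.
#' @method tidy gf_ensemble
#' @export
tidy.gf_ensemble <- function(x, ...) {
  x$partition_final |>
    left_join(x$partition_gini |> rename(gini_cluster = "cluster"),
              by = "cell_id") |>
    left_join(x$partition_fano |> rename(fano_cluster = "cluster"),
              by = "cell_id") |>
    left_join(x$weights |> select("cell_id", "w_tilde_g"), by = "cell_id") |>
    select("cell_id", "gini_cluster", "fano_cluster", "cluster", "w_tilde_g")
}

#' Glance at a fitted ensemble
#'
#' @param x A `gf_ensemble` object.
#' @param ... Unused.
#' @return A one-row tibble of fit-level summaries (dimensions, k per
#'   stage, weighting parameters, seed, and agreement metrics when a
#'   reference was supplied).
#' @method glance gf_ensemble
#' @export
glance.gf_ensemble <- function(x, ...) {
  out <- tibble(
    n_genes = x$dims$filtered[1], n_cells = x$dims$filtered[2],
    n_high_gini = length(x$high_gini_genes),
    k_gini = x$k_gini, k_fano = x$k_fano, k_final = x$k_final,
    n_noise = sum(x$partition_gini$cluster == 0L),
    mu = x$params$mu, s = x$params$s, f = x$params$f,
    seed = x$options$seed)
  if (!is.null(x$metrics)) {
    out$ari <- x$metrics$ari
    out$nmi <- x$metrics$nmi
  }
  out
}

#' Plot a fitted ensemble
#'
#' Composite tSNE panels colored by the consensus clusters. Requires the
#' fit to have been run with `compute_tsne = TRUE` (or supply coordinates).
#'
#' @param object A `gf_ensemble` object.
#' @param coords Optional coordinates from [composite_tsne()].
#' @param ... Unused.
#' @return A `ggplot` object.
#' @method autoplot gf_ensemble
#' @export
autoplot.gf_ensemble <- function(object, coords = NULL, ...) {
  coords <- coords %||% object$tsne
  if (is.null(coords)) {
    abort("no tSNE coordinates; run with compute_tsne = TRUE or pass coords")
  }
  plot_composite(coords, object$partition_final)
}

#' Write a JSON run report
#'
#' Records dimensions, per-stage cluster counts, parameter values, seed,
#' per-cluster sizes, timings, and (when available) agreement metrics.
#'
#' @param x A `gf_ensemble` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  sizes <- partition_sizes(x$partition_final)
  rep <- list(
    package_version = as.character(utils::packageVersion("ginifano")),
    dims = x$dims, k_gini = x$k_gini, k_fano = x$k_fano,
    k_final = x$k_final, n_high_gini = length(x$high_gini_genes),
    params = x$params[c("mu", "s", "f", "mu_prime", "s_prime", "f_prime")],
    options = x$options,
    cluster_sizes = setNames(sizes$n_cells, sizes$cluster),
    timings = x$timings)
  if (!is.null(x$metrics)) {
    rep$metrics <- list(ari = x$metrics$ari, nmi = x$metrics$nmi)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
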