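#' Composite tSNE coordinates
#'
#' Builds the three-dimensional composite view used to visualize both
#' common and rare structure: one tSNE dimension computed from the
#' Gini-based (Jaccard) cell-cell distance and two tSNE dimensions computed
#' from the Fano-based PCA embedding. The two common-cell dimensions
#' separate the large clusters; the third, rare-cell dimension separates
#' the small clusters that overlap in the common-cell map. The composite is
#' not a single projection of one feature space but the juxtaposition of
#' two complementary views, so distances between the axes have no joint
#' interpretation.
#'
#' For data sets larger than `pca_gini_threshold` cells the 1-D tSNE runs
#' on the first 50 principal components of the Gini distance rows instead
#' of the full distance matrix, which keeps tSNE tractable.
#'
#' @param gini_dist Symmetric Gini-based distance matrix (see
#'   [jaccard_distance()]).
#' @param fano_embedding PCA embedding, cells x components (see
#'   [pca_reduce()]).
#' @param seed Integer seed; coordinates are deterministic given the seed.
#' @param perplexity tSNE perplexity; default `min(30, (n - 1) / 3)`.
#' @param pca_gini_threshold Cell count above which the Gini distance is
#'   reduced to 50 PCs first.
#' @param max_iter tSNE iterations.
#' @return Tibble with columns `cell_id`, `gini1`, `fano1`, `fano2`.
#' @export
composite_tsne <- function(gini_dist, fano_embedding, seed = 1L,
                           perplexity = NULL, pca_gini_threshold = 5000,
                           max_iter = 500) {
  n <- nrow(fano_embedding)
  if (nrow(gini_dist) != n) {
    abort("gini_dist and fano_embedding disagree on the number of cells")
  }
  ids <- rownames(fano_embedding) %||% rownames(gini_dist) %||%
    as.character(seq_len(n))
  if (is.null(perplexity)) perplexity <- min(30, floor((n - 1) / 3))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  set.seed(seed)
  if (n > pca_gini_threshold) {
    gpc <- prcomp(gini_dist, rank. = 50)$x
    g1 <- Rtsne::Rtsne(gpc, dims = 1, perplexity = perplexity,
                       pca = FALSE, max_iter = max_iter,
                       check_duplicates = FALSE)$Y
  } else {
    g1 <- Rtsne::Rtsne(stats::as.dist(gini_dist), dims = 1,
                       perplexity = perplexity, is_distance = TRUE,
                       max_iter = max_iter)$Y
  }
  set.seed(seed + 1L)
  f2 <- Rtsne::Rtsne(fano_embedding, dims = 2, perplexity = perplexity,
                     pca = FALSE, max_iter = max_iter,
                     check_duplicates = FALSE)$Y
  tibble(cell_id = ids, gini1 = g1[, 1], fano1 = f2[, 1], fano2 = f2[, 2])
}

#' Plot a composite tSNE
#'
#' Two linked panels of the 3-D composite view: the common-cell map
#' (`fano1` vs `fano2`) and the rare-cell axis (`fano1` vs `gini1`),
#' colored by cluster.
#'
#' @param coords Tibble from [composite_tsne()].
#' @param partition Optional partition tibble used to color cells.
#' @return A `ggplot` object.
#' @export
plot_composite <- function(coords, partition = NULL) {
  df <- coords
  if (!is.null(partition)) {
    p <- as_partition(partition)
    df <- df |> left_join(p, by = "cell_id") |>
      mutate(cluster = factor(.data$cluster))
  } else {
    df$cluster <- factor(1)
  }
  long <- dplyr::bind_rows(
    df |> mutate(panel = "common-cell map", xx = .data$fano1, yy = .data$fano2),
    df |> mutate(panel = "rare-cell axis", xx = .data$fano1, yy = .data$gini1))
  ggplot2::ggplot(long, ggplot2::aes(.data$xx, .data$yy, color = .data$cluster)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "fano tSNE 1", y = "fano tSNE 2 / gini tSNE 1",
                  color = "cluster") +
    ggplot2::theme_minimal()
}
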