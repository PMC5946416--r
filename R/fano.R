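#' Fano factor of an expression vector
#'
#' Variance over mean expression. High Fano-factor genes vary across
#' common cell types and form the feature space of the common-cell
#' clustering stage. Uses the sample (n-1) variance; genes with zero mean
#' are assigned a Fano factor of 0 by convention. Scales linearly:
#' `fano_factor(c * x) == c * fano_factor(x)` for `c > 0`.
#'
#' @param x Numeric vector of expression values, length >= 2.
#' @return Non-negative number.
#' @examples
#' fano_factor(c(0, 4)) # sample variance 8 over mean 2 = 4
#' @export
fano_factor <- function(x) {
  if (length(x) < 2) abort("fano_factor needs at least 2 values")
  m <- mean(x)
  if (m <= 0) return(0)
  var(x) / m
}

#' Per-gene Fano factors
#'
#' @param m Count matrix, genes x cells.
#' @return Tibble with columns `gene_id`, `mean_expr`, `fano`.
#' @export
score_fano <- function(m) {
  n <- ncol(m)
  if (n < 2) abort("need at least 2 cells")
  mu <- Matrix::rowSums(m) / n
  ex2 <- Matrix::rowSums(m^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  tibble(gene_id = rownames(m), mean_expr = as.numeric(mu),
         fano = ifelse(mu > 0, as.numeric(v / mu), 0))
}

#' Combined per-gene scores
#'
#' One record per gene of the filtered matrix, carrying both feature
#' statistics used by the pipeline: maximum expression, raw and normalized
#' Gini index with p-value, and Fano factor.
#'
#' @param m Count matrix, genes x cells.
#' @inheritParams normalize_gini
#' @return Tibble with columns `gene_id`, `max_expr`, `gini_raw`,
#'   `gini_norm`, `p_value`, `mean_expr`, `fano`.
#' @export
score_genes <- function(m, span = 0.9, outlier_quantile = 0.9,
                        center = c("mean", "median")) {
  score_gini(m) |>
    normalize_gini(span = span, outlier_quantile = outlier_quantile,
                   center = center) |>
    left_join(score_fano(m), by = "gene_id")
}

#' Select top Fano-factor genes
#'
#' The `n_genes` genes with the largest Fano factor, ties broken by
#' lexicographic gene id so the selection is deterministic. If fewer genes
#' exist, all are returned with a warning.
#'
#' @param m Count matrix, genes x cells.
#' @param n_genes Number of genes to select.
#' @return Character vector of selected gene ids.
#' @export
select_top_fano <- function(m, n_genes = 1000) {
  stopifnot(n_genes >= 1)
  sc <- score_fano(m)
  if (nrow(sc) <= n_genes) {
    if (nrow(sc) < n_genes) {
      warn(sprintf("only %d genes available (requested %d); returning all",
                   nrow(sc), n_genes))
    }
    return(sc$gene_id[order(-sc$fano, sc$gene_id)])
  }
  sc$gene_id[order(-sc$fano, sc$gene_id)][seq_len(n_genes)]
}

#' PCA reduction of the expression matrix
#'
#' Principal component analysis of the cells-by-genes matrix after
#' per-gene centering, via singular value decomposition. The number of
#' effective components is `min(n_components, n_cells - 1, n_genes)`. The
#' sign of each component is fixed by forcing its largest-magnitude gene
#' loading to be positive, so the embedding is fully deterministic.
#'
#' @param m Count matrix restricted to the selected genes, genes x cells.
#' @param n_components Number of principal components to keep.
#' @param transform `"none"` (raw counts, the default) or `"log1p"`.
#' @return Matrix, cells x components, with cell-id rownames and
#'   attributes `"sdev"` (component standard deviations) and `"rotation"`
#'   (gene loadings).
#' @export
pca_reduce <- function(m, n_components = 50, transform = c("none", "log1p")) {
  stopifnot(n_components >= 1)
  transform <- match.arg(transform)
  x <- t(as.matrix(m)) # cells x genes
  if (transform == "log1p") x <- log1p(x)
  x <- scale(x, center = TRUE, scale = FALSE)
  k <- min(n_components, nrow(x) - 1, ncol(x))
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 1)
  flip[flip == 0] <- 1
  emb <- sv$u %*% diag(sv$d[seq_len(k)] * flip, nrow = k)
  rot <- sweep(sv$v, 2, flip, "*")
  rownames(emb) <- colnames(m)
  colnames(emb) <- paste0("PC", seq_len(k))
  rownames(rot) <- rownames(m)
  colnames(rot) <- colnames(emb)
  attr(emb, "sdev") <- sv$d[seq_len(k)] / sqrt(max(1, nrow(x) - 1))
  attr(emb, "rotation") <- rot
  emb
}

#' k-means with kmeans++ restarts
#'
#' Lloyd k-means (at most 300 iterations per run) with `n_restarts`
#' independent kmeans++ initializations; the run with the lowest total
#' within-cluster sum of squares is returned. Fully deterministic given
#' `seed`: restarts draw from one sequential RNG stream, so the best
#' objective over `1..m` restarts is non-increasing in `m`.
#'
#' @param e Numeric matrix, cells x features (e.g. a PCA embedding or the
#'   rows of a consensus matrix).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param n_restarts Number of kmeans++ restarts.
#' @param seed Integer seed.
#' @return A partition tibble with attributes `objective` (total
#'   within-cluster sum of squares), `k`, and `centers`.
#' @export
kmeans_cluster <- function(e, k, n_restarts = 20, seed = 1L) {
  n <- nrow(e)
  if (k > n) abort("k exceeds the number of cells")
  stopifnot(k >= 1, n_restarts >= 1)
  ids <- rownames(e) %||% as.character(seq_len(n))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cen <- kmeanspp_init(e, k)
    fit <- tryCatch(
      suppressWarnings(kmeans(e, centers = cen, iter.max = 300,
                              algorithm = "Lloyd")),
      error = function(err) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) abort("k-means failed in every restart")
  out <- new_partition(ids, best$cluster)
  attr(out, "objective") <- best$tot.withinss
  attr(out, "k") <- k
  attr(out, "centers") <- best$centers
  out
}

# kmeans++ seeding: subsequent centers sampled proportional to squared
# distance from the nearest chosen center
kmeanspp_init <- function(e, k) {
  n <- nrow(e)
  idx <- sample.int(n, 1)
  if (k == 1) return(e[idx, , drop = FALSE])
  d2 <- rowSums(sweep(e, 2, e[idx, ], "-")^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      idx <- c(idx, sample.int(n, 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = d2 / sum(d2)))
    }
    d2 <- pmin(d2, rowSums(sweep(e, 2, e[idx[j], ], "-")^2))
  }
  e[idx, , drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Choose k with the gap statistic
#'
#' Runs [cluster::clusGap()] on the embedding with the package's k-means
#' (kmeans++ restarts) as the clustering function. Reference data sets are
#' drawn uniformly over the principal-component-aligned bounding box of the
#' data (`spaceH0 = "scaledPCA"`), and k is picked with the `firstSEmax`
#' rule: the smallest k whose gap is within one standard error of the
#' first local maximum.
#'
#' Within-cluster dispersion uses unsquared distances (`d_power = 1`), the
#' convention of the canonical `clusGap` implementation. This matters for
#' scRNA-seq embeddings that contain a few far outliers (rare cells):
#' with squared distances the outliers' quadratic contribution rewards
#' splitting them off as a spurious extra cluster, while the unsquared
#' form keeps the statistic focused on the bulk structure. The
#' squared-distance variant of the original gap-statistic formulation is
#' available via `d_power = 2`.
#'
#' @param e Embedding matrix, cells x components.
#' @param k_max Largest k to evaluate (>= 2).
#' @param n_refs Number of uniform reference data sets.
#' @param seed Integer seed.
#' @param n_restarts kmeans++ restarts per k-means call (smaller than the
#'   final-clustering default; the gap curve averages over many fits).
#' @param d_power Power applied to distances in the dispersion.
#' @return Integer k, with the clusGap table in attribute `"gap_table"`.
#' @export
choose_k_gap <- function(e, k_max = 5, n_refs = 20, seed = 1L, n_restarts = 5,
                         d_power = 1) {
  stopifnot(k_max >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fun <- function(x, k) {
    list(cluster = partition_vector(
      kmeans_cluster(x, k, n_restarts = n_restarts,
                     seed = sample.int(.Machine$integer.max, 1))))
  }
  cg <- cluster::clusGap(e, FUNcluster = fun, K.max = k_max, B = n_refs,
                         d.power = d_power, spaceH0 = "scaledPCA",
                         verbose = FALSE)
  tab <- cg$Tab
  k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"], method = "firstSEmax")
  attr(k, "gap_table") <- as_tibble(tab) |> mutate(k = dplyr::row_number())
  k
}
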