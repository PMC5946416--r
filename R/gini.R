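#' Gini index of an expression vector
#'
#' The Gini index is twice the area between the Lorenz curve of a gene's
#' expression across cells and the diagonal. It is high when expression is
#' concentrated in few cells, which makes it an effective selector of
#' rare-cell marker genes. Computed here via the O(n log n) sorted form
#'
#' \deqn{G = \frac{2 \sum_i i\, x_{(i)}}{n \sum_i x_i} - \frac{n+1}{n},}
#'
#' which equals the pairwise mean-absolute-difference form
#' \eqn{\sum_{ij} |x_i - x_j| / (2 n^2 \bar x)}. Scale-invariant; 0 for a
#' constant (or all-zero, by convention) vector; bounded above by
#' \eqn{(n-1)/n < 1}.
#'
#' @param x Numeric vector of non-negative expression values, length >= 2.
#' @return Gini index in `[0, 1)`.
#' @examples
#' gini_index(c(5, 5, 5, 5)) # 0
#' gini_index(c(4, 2, 2))    # 1/6
#' @export
gini_index <- function(x) {
  if (length(x) < 2) abort("gini_index needs at least 2 values")
  if (any(x < 0)) abort("gini_index requires non-negative values")
  gini_sorted_nz(sort(x[x > 0]), length(x))
}

# Gini from the ascending nonzero values plus the total length.
# Zeros occupy the lowest ranks and contribute nothing to the numerator.
gini_sorted_nz <- function(nz_sorted, n) {
  s <- sum(nz_sorted)
  if (s <= 0) return(0)
  z <- n - length(nz_sorted)
  2 * sum((z + seq_along(nz_sorted)) * nz_sorted) / (n * s) - (n + 1) / n
}

#' Per-gene Gini scores
#'
#' Computes, for every gene, the maximum expression across cells and the
#' raw Gini index. Use [normalize_gini()] afterwards to remove the trend
#' with maximum expression and obtain p-values.
#'
#' @param m Count matrix, genes x cells.
#' @return Tibble with columns `gene_id`, `max_expr`, `gini_raw`.
#' @export
score_gini <- function(m) {
  if (ncol(m) < 2) abort("need at least 2 cells")
  mt <- methods::as(Matrix::t(m), "CsparseMatrix") # cells x genes: gene-major
  p <- mt@p
  xs <- mt@x
  n <- ncol(m)
  g <- nrow(m)
  gini <- numeric(g)
  mx <- numeric(g)
  for (j in seq_len(g)) {
    if (p[j + 1] > p[j]) {
      vals <- xs[(p[j] + 1):p[j + 1]]
      mx[j] <- max(vals)
      gini[j] <- gini_sorted_nz(sort(vals), n)
    }
  }
  tibble(gene_id = rownames(m), max_expr = mx, gini_raw = gini)
}

#' Normalize Gini scores and assign p-values
#'
#' The raw Gini index decreases with expression level, so it is normalized
#' by removing the trend with maximum expression through a two-step LOESS
#' regression: a first LOESS of `gini_raw` on `log2(max_expr + 0.1)` over
#' all genes, then a refit that excludes genes whose first-pass residual
#' lies above a high quantile (so that genuinely high-Gini genes do not
#' drag the trend up). The normalized Gini is the residual from the second
#' fit; prediction sites are clamped to the refit's covariate range so
#' excluded extreme genes still receive a trend value. One-sided upper-tail
#' p-values are computed under a normal distribution whose location and
#' scale are estimated from all normalized values (`center = "mean"`, the
#' default) or robustly via median/MAD (`center = "median"`).
#'
#' @param scores Tibble from [score_gini()].
#' @param span,degree LOESS smoothing parameters.
#' @param outlier_quantile First-pass residual quantile above which genes
#'   are excluded from the second fit.
#' @param center `"mean"` (moment estimates) or `"median"` (median/MAD).
#' @return `scores` with columns `gini_norm` and `p_value` added.
#' @export
normalize_gini <- function(scores, span = 0.9, degree = 1,
                           outlier_quantile = 0.9,
                           center = c("mean", "median")) {
  center <- match.arg(center)
  if (sum(scores$max_expr > 0) < 10) {
    abort("need at least 10 genes with nonzero expression; provide a larger input")
  }
  lx <- log2(scores$max_expr + 0.1)
  # fine interpolation cells so the fitted surface reproduces the local
  # regressions to machine precision
  ctrl <- loess.control(cell = 0.05)
  fit1 <- tryCatch(loess(scores$gini_raw ~ lx, span = span, degree = degree,
                         control = ctrl),
                   error = function(e) abort(paste0(
                     "LOESS fit failed (", conditionMessage(e),
                     "); provide a larger input")))
  r1 <- scores$gini_raw - predict(fit1, lx)
  keep <- r1 <= quantile(r1, outlier_quantile, na.rm = TRUE) & !is.na(r1)
  fit2 <- loess(scores$gini_raw[keep] ~ lx[keep], span = span, degree = degree,
                control = ctrl)
  rng <- range(lx[keep])
  trend <- predict(fit2, pmin(pmax(lx, rng[1]), rng[2]))
  gini_norm <- scores$gini_raw - trend
  scores |>
    mutate(gini_norm = gini_norm,
           p_value = gini_pvalue(gini_norm, center = center))
}

# upper-tail normal p-values for normalized Gini values
gini_pvalue <- function(gini_norm, center = c("mean", "median")) {
  center <- match.arg(center)
  if (center == "mean") {
    loc <- mean(gini_norm); sc <- sd(gini_norm)
  } else {
    loc <- median(gini_norm); sc <- mad(gini_norm)
  }
  pnorm(gini_norm, mean = loc, sd = sc, lower.tail = FALSE)
}

#' Select high-Gini genes
#'
#' Genes whose normalized Gini index is significantly above zero
#' (p-value strictly below `p_threshold` under the normal assumption) are
#' labeled high-Gini genes; they form the feature space of the rare-cell
#' clustering stage.
#'
#' @param scores Tibble with a `p_value` column (see [normalize_gini()]).
#' @param p_threshold Selection threshold (strict inequality).
#' @return Character vector of selected gene ids.
#' @export
select_high_gini <- function(scores, p_threshold = 1e-4) {
  if (!"p_value" %in% names(scores)) {
    abort("scores lack p_value; run normalize_gini() first")
  }
  sel <- scores$gene_id[scores$p_value < p_threshold]
  if (length(sel) == 0) {
    abort(paste0("no gene passes p < ", format(p_threshold),
                 "; relax the threshold (the rare-cell stage needs Gini features)"))
  }
  sel
}

#' Jaccard distance between cells
#'
#' Binarizes each cell's profile (count > 0) over the supplied genes and
#' returns the pairwise Jaccard distance
#' \eqn{d(i,j) = 1 - |A_i \cap A_j| / |A_i \cup A_j|}, where \eqn{A_i} is
#' the set of genes detected in cell i. Two cells expressing none of the
#' genes are at distance 0 by convention.
#'
#' @param m Count matrix restricted to the selected (high-Gini) genes.
#' @return Dense symmetric n x n matrix with zero diagonal and cell-id
#'   dimnames.
#' @export
jaccard_distance <- function(m) {
  if (nrow(m) < 1 || ncol(m) < 2) abort("need >= 1 gene and >= 2 cells")
  b <- methods::as(m > 0, "dMatrix") * 1
  inter <- as.matrix(Matrix::crossprod(b))
  sz <- Matrix::colSums(b)
  uni <- outer(sz, sz, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' DBSCAN on a precomputed distance matrix
#'
#' Density-based clustering used by the rare-cell stage on the Jaccard
#' distance. A cell is a core point when its eps-neighborhood (the point
#' itself included) holds at least `min_pts` cells; clusters grow from core
#' points in cell order, so the result is deterministic for a fixed cell
#' ordering. Cells reachable from no core point are labeled noise
#' (cluster `0`). An all-noise result is legal and is treated downstream as
#' "no rare structure".
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param eps Neighborhood radius.
#' @param min_pts Minimum neighborhood size (self included) for a core point.
#' @return A partition tibble (see [new_partition()]).
#' @export
dbscan_cluster <- function(d, eps = 0.5, min_pts = 3) {
  stopifnot(eps > 0, min_pts >= 1)
  if (!isTRUE(all.equal(unname(d), unname(t(d)))) || any(diag(d) != 0)) {
    abort("distance matrix must be symmetric with zero diagonal")
  }
  n <- nrow(d)
  ids <- rownames(d) %||% as.character(seq_len(n))
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbr, length, 1L) >= min_pts
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cid <- cid + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cid
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      for (j in nbr[[q]]) {
        if (labels[j] == 0L) labels[j] <- cid
        if (core[j] && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  new_partition(ids, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
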