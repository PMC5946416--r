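#' Connectivity matrix of a partition
#'
#' Binary cell-by-cell matrix with entry 1 when two cells share a cluster.
#' Noise cells (label 0) connect only to themselves; the diagonal is
#' always 1.
#'
#' @param p A partition tibble (see [new_partition()]).
#' @return Dense symmetric 0/1 matrix with unit diagonal and cell-id
#'   dimnames.
#' @export
connectivity <- function(p) {
  p <- as_partition(p)
  lab <- p$cluster
  m <- outer(lab, lab, function(a, b) as.numeric(a == b & a != 0L))
  diag(m) <- 1
  dimnames(m) <- list(p$cell_id, p$cell_id)
  m
}

#' Weighting parameters for the consensus stage
#'
#' The consensus stage mixes the two connectivity matrices with cell-pair
#' weights driven by a logistic curve over cluster-size proportion. Users
#' specify the interpretable triple:
#' * `mu` — the cluster-size proportion at which the rare-cell and
#'   common-cell methods are trusted equally,
#' * `s` — how quickly the rare-cell method loses its edge above `mu`,
#' * `f` — the overall importance of the common-cell (Fano) membership,
#'   as a proportion in (0, 0.5).
#'
#' Internally these map to the primed parameters of the logistic weight
#' curve: `f' = f / (1 - f)` (the constant Fano cell weight), `s' = s`,
#' and `mu' = mu + s' * logit(f')`, which inverts the defining relation
#' `f' = 1 - 1/(1 + exp(-(mu - mu')/s'))`. The inverse map
#' [recover_params()] round-trips to machine precision. `f` must stay
#' below 0.5: at `f = 0.5` the defining relation has no finite `mu'`
#' (`f' = 1` is the supremum of the logistic curve).
#'
#' @param mu Proportion in (0, 1).
#' @param s Positive scale.
#' @param f Proportion in (0, 0.5).
#' @return An object of class `weight_params`: a list with `mu`, `s`, `f`,
#'   `mu_prime`, `s_prime`, `f_prime`.
#' @examples
#' derive_params(mu = 0.05, s = 0.0125, f = 0.025)
#' @export
derive_params <- function(mu = 0.05, s = 0.0125, f = 0.025) {
  if (!(f > 0 && f < 1)) abort("f must lie in (0, 1)")
  if (f >= 0.5) {
    abort("f must lie below 0.5: the logistic link between mu and mu' requires f' = f/(1-f) < 1")
  }
  if (!(mu > 0 && mu < 1)) abort("mu must lie in (0, 1)")
  if (s <= 0) abort("s must be positive")
  f_prime <- f / (1 - f)
  s_prime <- s
  mu_prime <- mu + s_prime * log(f_prime / (1 - f_prime))
  structure(list(mu = mu, s = s, f = f,
                 mu_prime = mu_prime, s_prime = s_prime, f_prime = f_prime),
            class = "weight_params")
}

#' @rdname derive_params
#' @param mu_prime,s_prime,f_prime Primed (internal) parameters; `f_prime`
#'   in (0, 1).
#' @return `recover_params()`: the user-facing triple `(mu, s, f)` as a
#'   list.
#' @export
recover_params <- function(mu_prime, s_prime, f_prime) {
  stopifnot(f_prime > 0, f_prime < 1, s_prime > 0)
  list(mu = mu_prime + s_prime * log((1 - f_prime) / f_prime),
       s = s_prime,
       f = f_prime / (1 + f_prime))
}

#' @export
print.weight_params <- function(x, ...) {
  cat("Consensus weighting parameters\n")
  cat(sprintf("  mu = %g, s = %g, f = %g\n", x$mu, x$s, x$f))
  cat(sprintf("  (mu' = %g, s' = %g, f' = %g)\n", x$mu_prime, x$s_prime, x$f_prime))
  invisible(x)
}

#' Cell-specific rare-stage weight
#'
#' Logistic weight of the rare-cell (Gini) partition for a cell whose
#' cluster holds a proportion `x` of all cells:
#' \deqn{\tilde w^G(x) = 1 - \frac{1}{1 + e^{-(x - \mu')/s'}}.}
#' Strictly decreasing in `x`: cells in small clusters trust the rare-cell
#' method, cells in large clusters the common-cell method.
#'
#' @param x Cluster-size proportion(s) in (0, 1].
#' @param params A `weight_params` object from [derive_params()].
#' @return Weight(s) in (0, 1).
#' @export
gini_cell_weight <- function(x, params) {
  stopifnot(inherits(params, "weight_params"))
  if (any(x <= 0 | x > 1)) abort("cluster proportions must lie in (0, 1]")
  1 - 1 / (1 + exp(-(x - params$mu_prime) / params$s_prime))
}

#' Per-cell consensus weights
#'
#' Computes each cell's cluster-size proportion under the rare-cell (Gini)
#' partition and the corresponding logistic weight. Noise cells receive
#' weight 0 (the rare-cell stage offers no confident assignment for them,
#' so the common-cell partition decides); their proportion is reported as
#' `NA`. Proportions use the total cell count, noise included, as the
#' denominator.
#'
#' @param p_gini Rare-stage partition tibble.
#' @param params A `weight_params` object.
#' @return Tibble with columns `cell_id`, `x` (cluster proportion), and
#'   `w_tilde_g`; the constant Fano cell weight `f'` is attached as
#'   attribute `"w_tilde_f"`.
#' @export
cell_weights <- function(p_gini, params) {
  p_gini <- as_partition(p_gini)
  n <- nrow(p_gini)
  sizes <- table(p_gini$cluster)
  x <- as.numeric(sizes[as.character(p_gini$cluster)]) / n
  x[p_gini$cluster == 0L] <- NA_real_
  w <- ifelse(is.na(x), 0, gini_cell_weight(ifelse(is.na(x), 0.5, x), params))
  out <- tibble(cell_id = p_gini$cell_id, x = x, w_tilde_g = w)
  attr(out, "w_tilde_f") <- params$f_prime
  out
}

#' Pair weights from cell weights
#'
#' A cell pair's rare-stage weight is the maximum of the two cell weights
#' (a pair is judged by its more rare member); the common-stage weight is
#' the constant `f'`. Both are then normalized to sum to 1.
#'
#' @param w_i,w_j Rare-stage cell weights in `[0, 1]` (vectorized).
#' @param f_prime Constant common-stage cell weight, positive.
#' @return Tibble with columns `w_g` and `w_f`, each pair summing to 1.
#' @export
pair_weights <- function(w_i, w_j, f_prime) {
  wg_t <- pmax(w_i, w_j)
  if (any(wg_t + f_prime == 0)) {
    abort("degenerate weights: both the pair weight and f' are zero")
  }
  tibble(w_g = wg_t / (wg_t + f_prime), w_f = f_prime / (wg_t + f_prime))
}

#' Weighted consensus association matrix
#'
#' Entrywise convex combination of the two connectivity matrices,
#' \eqn{\bar M_{ij} = w^G_{ij} M_{ij}(P^G) + w^F_{ij} M_{ij}(P^F)}, with
#' pair weights from [pair_weights()]. Each entry lies between the two
#' connectivities and can be read as the probability that cells i and j
#' share a cluster. Rows are computed in blocks of `block_size` so peak
#' additional memory beyond the output stays O(block_size x n).
#'
#' @param p_gini,p_fano The two partitions (must cover the same cells).
#' @param params A `weight_params` object.
#' @param block_size Number of rows computed per block.
#' @return Dense symmetric n x n matrix in `[0, 1]` with unit diagonal.
#' @export
consensus_matrix <- function(p_gini, p_fano, params, block_size = 1024) {
  p_gini <- as_partition(p_gini)
  p_fano <- as_partition(p_fano)
  cells <- align_cells(p_gini, p_fano)
  n <- length(cells)
  lab_g <- unname(partition_vector(p_gini, cells))
  lab_f <- unname(partition_vector(p_fano, cells))
  w <- cell_weights(p_gini, params)
  wg <- w$w_tilde_g[match(cells, w$cell_id)]
  fp <- params$f_prime
  out <- matrix(0, n, n, dimnames = list(cells, cells))
  for (start in seq(1, n, by = block_size)) {
    rows <- start:min(start + block_size - 1, n)
    mg <- outer(lab_g[rows], lab_g, function(a, b) as.numeric(a == b & a != 0L))
    mf <- outer(lab_f[rows], lab_f, function(a, b) as.numeric(a == b))
    wij <- outer(wg[rows], wg, pmax)
    wgn <- wij / (wij + fp)
    out[rows, ] <- wgn * mg + (1 - wgn) * mf
  }
  diag(out) <- 1
  out
}

#' Final consensus clustering
#'
#' Extracts a hard clustering from the consensus association matrix by
#' minimizing \eqn{\|\bar M - U\|^2} over connectivity matrices U with k
#' blocks. With an orthogonality constraint this optimization reduces to
#' k-means on the rows of the consensus matrix, which is how it is solved
#' here (see [kmeans_cluster()]).
#'
#' @param mbar Consensus matrix from [consensus_matrix()].
#' @param k_final Number of consensus clusters.
#' @param n_restarts,seed Passed to [kmeans_cluster()].
#' @return A partition tibble with the k-means attributes.
#' @export
final_cluster <- function(mbar, k_final, n_restarts = 20, seed = 1L) {
  if (k_final > nrow(mbar)) abort("k_final exceeds the number of cells")
  stopifnot(k_final >= 1)
  kmeans_cluster(mbar, k_final, n_restarts = n_restarts, seed = seed)
}

#' Default rule for the final cluster count
#'
#' The number of consensus clusters defaults to the number of common
#' (Fano) clusters plus the number of rare candidates from the Gini
#' partition: clusters whose size proportion falls below `mu` (and which
#' are not majority-contained in a previously counted candidate; Gini
#' clusters are disjoint, so this guard is only reachable for degenerate
#' inputs). Override by passing an explicit `k_final` to the pipeline.
#'
#' @param p_gini,p_fano The two partitions.
#' @param params A `weight_params` object (`mu` is the rare threshold).
#' @return Integer k, with a tibble of the counted rare candidates in
#'   attribute `"rare_candidates"`.
#' @export
choose_k_final <- function(p_gini, p_fano, params) {
  p_gini <- as_partition(p_gini)
  sizes <- partition_sizes(p_gini) |> filter(.data$cluster != 0L)
  rare <- sizes |> filter(.data$prop < params$mu)
  counted <- integer(0)
  for (cl in rare$cluster) {
    members <- p_gini$cell_id[p_gini$cluster == cl]
    overlap <- vapply(counted, function(prev) {
      mean(members %in% p_gini$cell_id[p_gini$cluster == prev])
    }, 1)
    if (!length(overlap) || max(overlap) <= 0.5) counted <- c(counted, cl)
  }
  k <- partition_k(p_fano) + length(counted)
  attr(k, "rare_candidates") <- rare |> filter(.data$cluster %in% counted)
  k
}
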