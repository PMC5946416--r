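#' Matthews correlation coefficient
#'
#' Balanced agreement score for a binary classification,
#' \deqn{\mathrm{MCC} = \frac{tp\,tn - fp\,fn}{\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}},}
#' ranging from -1 (total disagreement) through 0 (no better than chance)
#' to 1 (perfect agreement). If any factor of the denominator is zero the
#' value is 0 by the standard convention.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts, not all zero.
#' @return Number in `[-1, 1]`.
#' @examples
#' mcc(tp = 2, tn = 2, fp = 1, fn = 1) # 1/3
#' @export
mcc <- function(tp, tn, fp, fn) {
  tp <- as.double(tp); tn <- as.double(tn)
  fp <- as.double(fp); fn <- as.double(fn)
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  if (all(counts == 0)) abort("all four confusion counts are zero")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Per-type MCC of a clustering against reference labels
#'
#' Measures a clustering's ability to detect each reference cell type. For
#' every type, the predicted cluster with the largest overlap (ties broken
#' toward the larger cluster, then the smaller label) defines the positive
#' prediction set, and a one-vs-rest MCC is computed from the resulting
#' confusion counts.
#'
#' @param pred Predicted partition tibble.
#' @param ref Reference labels: a tibble with `cell_id` and a label column,
#'   or a named vector.
#' @return Tibble with one row per reference type: `type`, the matched
#'   `cluster`, the confusion counts, and `mcc`.
#' @export
mcc_per_type <- function(pred, ref) {
  pred <- as_partition(pred)
  ref <- ref_labels_tbl(ref)
  if (!all(pred$cell_id %in% ref$cell_id)) {
    abort("predicted partition contains cells absent from the reference")
  }
  if (!all(ref$cell_id %in% pred$cell_id)) {
    abort("reference contains cells absent from the predicted partition")
  }
  lab <- partition_vector(pred, ref$cell_id)
  cl_sizes <- table(lab)
  n <- nrow(ref)
  purrr::map_dfr(sort(unique(ref$type)), function(ty) {
    in_type <- ref$type == ty
    ov <- table(lab[in_type])
    cand <- as.integer(names(ov))
    best <- order(-as.numeric(ov),
                  -as.numeric(cl_sizes[names(ov)]),
                  cand)[1]
    cl <- cand[best]
    in_cl <- lab == cl
    tp <- sum(in_type & in_cl); fp <- sum(!in_type & in_cl)
    fn <- sum(in_type & !in_cl); tn <- sum(!in_type & !in_cl)
    tibble(type = ty, cluster = cl, tp = tp, fp = fp, fn = fn, tn = tn,
           mcc = mcc(tp, tn, fp, fn))
  })
}

ref_labels_tbl <- function(ref) {
  if (is.data.frame(ref)) {
    if (ncol(ref) < 2) abort("reference needs cell id and label columns")
    cols <- if (all(c("cell_id", "type") %in% names(ref))) {
      ref[c("cell_id", "type")]
    } else ref[1:2]
    return(tibble(cell_id = as.character(cols[[1]]),
                  type = as.character(cols[[2]])))
  }
  if (is.null(names(ref))) abort("reference vector must be named by cell id")
  tibble(cell_id = names(ref), type = as.character(ref))
}

#' Normalized mutual information between two partitions
#'
#' Entropy-based agreement score in `[0, 1]`, invariant under cluster
#' relabeling: 1 for identical partitions (up to renaming), ~0 for
#' independent ones. The mutual information is normalized by the
#' arithmetic mean of the two entropies by default; geometric-mean and
#' max normalizations are also available. When both partitions consist of
#' a single cluster, both entropies vanish and the value is 1 by
#' convention.
#'
#' @param p1,p2 Partition tibbles over the same cells.
#' @param normalization `"arithmetic"` (default), `"geometric"`, or
#'   `"max"`.
#' @return Number in `[0, 1]`.
#' @export
nmi <- function(p1, p2, normalization = c("arithmetic", "geometric", "max")) {
  normalization <- match.arg(normalization)
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  cells <- align_cells(p1, p2)
  a <- partition_vector(p1, cells)
  b <- partition_vector(p2, cells)
  tab <- table(a, b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  h1 <- -sum(pj * log(pj), na.rm = TRUE)
  h2 <- -sum(pk * log(pk), na.rm = TRUE)
  if (h1 == 0 && h2 == 0) return(1)
  pij <- tab / n
  ratio <- sweep(sweep(pij, 1, pj, "/"), 2, pk, "/")
  mi <- sum(pij * log(ifelse(pij > 0, ratio, 1)))
  den <- switch(normalization,
                arithmetic = (h1 + h2) / 2,
                geometric = sqrt(h1 * h2),
                max = max(h1, h2))
  if (den == 0) return(0)
  min(1, max(0, mi / den))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions up
#' to relabeling, ~0 for independent ones.
#'
#' @param p1,p2 Partition tibbles over the same cells.
#' @return Number (at most 1).
#' @export
ari <- function(p1, p2) {
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  cells <- align_cells(p1, p2)
  tab <- table(partition_vector(p1, cells), partition_vector(p2, cells))
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Confusion map between a clustering and reference labels
#'
#' For every reference label, the proportion of its cells falling in each
#' predicted cluster. Rows (reference labels) sum to 1.
#'
#' @param pred Predicted partition tibble.
#' @param ref Reference labels (tibble or named vector).
#' @return Long-format tibble with columns `type`, `cluster`, and
#'   `proportion`; pivot wider for a matrix view.
#' @export
confusion_map <- function(pred, ref) {
  pred <- as_partition(pred)
  ref <- ref_labels_tbl(ref)
  lab <- partition_vector(pred, ref$cell_id)
  ref |>
    mutate(cluster = unname(lab)) |>
    count(.data$type, .data$cluster) |>
    group_by(.data$type) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup() |>
    select("type", "cluster", "proportion")
}
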