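#' Cell partitions
#'
#' Throughout the package a partition of cells into clusters is represented
#' as a tibble with two columns: `cell_id` (character) and `cluster`
#' (integer). Cluster labels run `1..k`; the label `0` is reserved for
#' DBSCAN noise cells, i.e. cells the rare-cell stage could not assign to
#' any dense region. `new_partition()` builds and validates such a tibble,
#' `as_partition()` coerces a named vector, factor, or two-column data
#' frame.
#'
#' @param cell_id Character vector of unique cell identifiers.
#' @param cluster Integer-like vector of cluster labels (`0` = noise).
#' @return A tibble with columns `cell_id` and `cluster`.
#' @examples
#' new_partition(c("a", "b", "c"), c(1, 1, 2))
#' @export
new_partition <- function(cell_id, cluster) {
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) {
    abort("duplicate cell identifiers in partition")
  }
  if (length(cell_id) != length(cluster)) {
    abort("cell_id and cluster must have the same length")
  }
  cl <- as.integer(cluster)
  if (anyNA(cl) || any(cl < 0L)) {
    abort("cluster labels must be non-negative integers (0 = noise)")
  }
  tibble(cell_id = cell_id, cluster = cl)
}

#' @rdname new_partition
#' @param x Object to coerce: a partition tibble, a named vector of labels,
#'   a factor, or a data frame whose first two columns are cell id and label.
#' @export
as_partition <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) abort("partition data frame needs cell id and label columns")
    cols <- if (all(c("cell_id", "cluster") %in% names(x))) {
      x[c("cell_id", "cluster")]
    } else {
      x[1:2]
    }
    lab <- cols[[2]]
    if (!is.numeric(lab)) lab <- as.integer(factor(lab))
    return(new_partition(cols[[1]], lab))
  }
  if (is.factor(x)) x <- setNames(as.integer(x), names(x))
  if (is.null(names(x))) {
    abort("cannot coerce an unnamed vector to a partition; names must be cell ids")
  }
  lab <- if (is.numeric(x)) x else as.integer(factor(x))
  new_partition(names(x), lab)
}

#' Summarise a partition
#'
#' @param p A partition tibble (see [new_partition()]).
#' @return A tibble with one row per cluster: `cluster`, `n_cells`, and
#'   `prop`, the cluster size divided by the total number of cells (noise
#'   cells included in the denominator, reported as cluster `0`).
#' @export
partition_sizes <- function(p) {
  p <- as_partition(p)
  p |>
    count(.data$cluster, name = "n_cells") |>
    mutate(prop = .data$n_cells / nrow(p)) |>
    arrange(.data$cluster)
}

#' @rdname partition_sizes
#' @return `partition_k()`: the number of clusters, noise excluded.
#' @export
partition_k <- function(p) {
  p <- as_partition(p)
  length(setdiff(unique(p$cluster), 0L))
}

#' @rdname partition_sizes
#' @param cells Optional cell ordering for the returned labels (defaults
#'   to the partition's own order).
#' @return `partition_vector()`: a named integer vector of labels.
#' @export
partition_vector <- function(p, cells = NULL) {
  p <- as_partition(p)
  if (is.null(cells)) {
    return(setNames(p$cluster, p$cell_id))
  }
  idx <- match(cells, p$cell_id)
  if (anyNA(idx)) {
    abort(paste0("cells absent from partition: ",
                 paste(head(cells[is.na(idx)], 3), collapse = ", ")))
  }
  setNames(p$cluster[idx], cells)
}

# check two partitions cover the same cells; return common cell order
align_cells <- function(p1, p2) {
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  if (!setequal(p1$cell_id, p2$cell_id)) {
    abort("partitions do not cover the same cells")
  }
  p1$cell_id
}
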