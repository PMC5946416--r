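#' Simulate UMI counts with planted common and rare clusters
#'
#' Generates a genes-by-cells matrix of negative-binomial UMI counts with
#' cluster-specific expression signatures, emulating the benchmark used to
#' validate the ensemble pipeline: two common clusters and four rare ones
#' by default (2000/1000/10/6/4/3 cells, 23,538 genes).
#'
#' Per-gene baseline means follow a zero-inflated log-normal law: a
#' fraction `p_silent` of genes is effectively silent (mean `silent_mean`),
#' mirroring real UMI data in which most annotated genes go undetected,
#' and the remaining genes draw their mean from
#' `lognormal(meanlog, sdlog)`. Counts are negative binomial with variance
#' `m + dispersion * m^2`, drawn independently per cell.
#'
#' Cluster signatures are created by label permutation: for each cluster a
#' disjoint set of `n_low_sig` lowly expressed genes (mean below
#' `low_mean_cutoff`) and `n_high_sig` highly expressed genes (mean above
#' the cutoff) is chosen, and within that cluster's cells the count rows of
#' the combined set are randomly shuffled among the selected genes. A
#' shuffle that moves fewer than half of the selected genes is re-drawn so
#' signatures stay non-trivial. Lowly expressed genes that inherit a highly
#' expressed gene's counts become markers of that cluster: strongly
#' expressed inside it, near-silent elsewhere.
#'
#' @param cluster_sizes Positive integers; cells per planted cluster.
#' @param n_genes Number of genes.
#' @param p_silent Fraction of silent genes.
#' @param silent_mean Baseline mean of silent genes.
#' @param meanlog,sdlog Log-normal parameters of expressed-gene means.
#' @param dispersion NB dispersion alpha in `v = m + alpha m^2`.
#' @param n_low_sig,n_high_sig Signature genes per cluster drawn from the
#'   low/high mean stratum (0 disables signatures).
#' @param low_mean_cutoff Mean separating the two strata.
#' @param seed Integer seed; the output is bit-identical for a fixed seed.
#' @return A list of class `sim_counts`:
#' \describe{
#'   \item{counts}{sparse `dgCMatrix`, genes x cells.}
#'   \item{labels}{ground-truth partition tibble (clusters `1..k`).}
#'   \item{gene_means}{tibble of per-gene baseline means.}
#'   \item{signatures}{per-cluster tibble of signature gene assignments
#'     (`gene_id` receives the counts of `source_gene`).}
#'   \item{config}{the parameters, echoed.}
#' }
#' @examples
#' sim <- simulate_counts(cluster_sizes = c(50, 30), n_genes = 400,
#'                        n_low_sig = 5, n_high_sig = 5, seed = 1)
#' dim(sim$counts)
#' @export
simulate_counts <- function(cluster_sizes = c(2000, 1000, 10, 6, 4, 3),
                            n_genes = 23538,
                            p_silent = 0.8, silent_mean = 1e-5,
                            meanlog = 1.6, sdlog = 0.8,
                            dispersion = 0.1,
                            n_low_sig = 100, n_high_sig = 100,
                            low_mean_cutoff = 10,
                            seed = 1L) {
  stopifnot(all(cluster_sizes >= 1), n_genes >= 1, dispersion > 0,
            n_low_sig >= 0, n_high_sig >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- sum(cluster_sizes)
  k <- length(cluster_sizes)
  gene_ids <- sprintf("gene_%0*d", nchar(n_genes), seq_len(n_genes))
  cell_ids <- sprintf("cell_%0*d", nchar(n), seq_len(n))
  labels <- rep(seq_len(k), cluster_sizes)

  silent <- runif(n_genes) < p_silent
  mu <- ifelse(silent, silent_mean, exp(rnorm(n_genes, meanlog, sdlog)))
  size_nb <- 1 / dispersion

  # baseline: each cell draws independently from every gene's NB law
  x <- matrix(0, n_genes, n)
  for (g in seq_len(n_genes)) {
    x[g, ] <- rnbinom(n, mu = mu[g], size = size_nb)
  }

  low <- which(mu < low_mean_cutoff)
  high <- which(mu > low_mean_cutoff)
  sigs <- vector("list", k)
  if (n_low_sig + n_high_sig > 0) {
    if (length(low) < k * n_low_sig) {
      abort(sprintf("low stratum (mean < %g) has %d genes; %d clusters x %d needed",
                    low_mean_cutoff, length(low), k, n_low_sig))
    }
    if (length(high) < k * n_high_sig) {
      abort(sprintf("high stratum (mean > %g) has %d genes; %d clusters x %d needed",
                    low_mean_cutoff, length(high), k, n_high_sig))
    }
    if (n_low_sig + n_high_sig < 2) {
      abort("need at least 2 signature genes per cluster to permute")
    }
    avail_low <- low
    avail_high <- high
    for (c in seq_len(k)) {
      gl <- sort(avail_low[sample.int(length(avail_low), n_low_sig)])
      gh <- sort(avail_high[sample.int(length(avail_high), n_high_sig)])
      avail_low <- setdiff(avail_low, gl)
      avail_high <- setdiff(avail_high, gh)
      sel <- c(gl, gh)
      repeat {
        perm <- sample(sel)
        if (sum(perm != sel) >= length(sel) / 2) break
      }
      cells_c <- which(labels == c)
      x[sel, cells_c] <- x[perm, cells_c]
      sigs[[c]] <- tibble(cluster = c,
                          gene_id = gene_ids[sel],
                          source_gene = gene_ids[perm],
                          stratum = rep(c("low", "high"), c(n_low_sig, n_high_sig)))
    }
  }

  dimnames(x) <- list(gene_ids, cell_ids)
  counts <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  structure(list(
    counts = counts,
    labels = new_partition(cell_ids, labels),
    gene_means = tibble(gene_id = gene_ids, mean = mu, silent = silent),
    signatures = dplyr::bind_rows(sigs),
    config = list(cluster_sizes = cluster_sizes, n_genes = n_genes,
                  p_silent = p_silent, silent_mean = silent_mean,
                  meanlog = meanlog, sdlog = sdlog, dispersion = dispersion,
                  n_low_sig = n_low_sig, n_high_sig = n_high_sig,
                  low_mean_cutoff = low_mean_cutoff, seed = seed)
  ), class = "sim_counts")
}

#' @export
print.sim_counts <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated UMI counts: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  planted clusters:", paste(cfg$cluster_sizes, collapse = "/"), "cells\n")
  cat(sprintf("  signatures: %d low + %d high genes per cluster (cutoff %g)\n",
              cfg$n_low_sig, cfg$n_high_sig, cfg$low_mean_cutoff))
  cat(sprintf("  seed: %d\n", cfg$seed))
  invisible(x)
}
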