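#' Read a UMI count matrix
#'
#' Loads a genes-by-cells matrix of UMI counts either from a 10X-style
#' Matrix Market directory (`matrix.mtx` plus `genes.tsv`/`features.tsv`
#' and `barcodes.tsv`) or from a dense delimited file with gene rows, cell
#' columns, and a header row of cell ids. The returned matrix is always
#' oriented genes x cells and validated: entries must be non-negative
#' integers and gene/cell identifiers must be unique.
#'
#' @param path Directory (for `mtx_dir`) or file (for `dense`).
#' @param format `"auto"` (directory implies `mtx_dir`), `"mtx_dir"`, or
#'   `"dense"` (TSV or CSV, chosen by extension).
#' @return A sparse `dgCMatrix`, genes x cells, with dimnames.
#' @seealso [filter_counts()], [write_counts()]
#' @export
read_counts <- function(path, format = c("auto", "mtx_dir", "dense")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("input path does not exist: ", path))
  }
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir" else "dense"
  }
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) abort(paste0("missing file: ", mtx))
    genes_f <- file.path(path, "genes.tsv")
    if (!file.exists(genes_f)) genes_f <- file.path(path, "features.tsv")
    if (!file.exists(genes_f)) {
      abort(paste0("missing file: ", file.path(path, "genes.tsv"),
                   " (or features.tsv)"))
    }
    bc_f <- file.path(path, "barcodes.tsv")
    if (!file.exists(bc_f)) abort(paste0("missing file: ", bc_f))
    m <- Matrix::readMM(mtx)
    genes <- readr::read_tsv(genes_f, col_names = FALSE, col_types = readr::cols(),
                             progress = FALSE)[[1]]
    cells <- readr::read_tsv(bc_f, col_names = FALSE, col_types = readr::cols(),
                             progress = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      abort("matrix dimensions do not match gene/barcode files")
    }
    dimnames(m) <- list(genes, cells)
    m <- methods::as(m, "CsparseMatrix")
  } else {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                            progress = FALSE)
    genes <- as.character(df[[1]])
    num <- as.matrix(df[-1])
    mode(num) <- "double"
    dimnames(num) <- list(genes, colnames(df)[-1])
    m <- methods::as(Matrix::Matrix(num, sparse = TRUE), "CsparseMatrix")
  }
  validate_counts(m)
  m
}

#' Validate a count matrix
#'
#' Checks the contract every downstream stage relies on: non-negative
#' integer-valued entries, unique gene ids, unique cell ids.
#'
#' @param m Matrix (dense or sparse), genes x cells, with dimnames.
#' @return `m`, invisibly, if valid; otherwise an error naming the first
#'   offending entry or identifier.
#' @export
validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("count matrix must carry gene ids (rownames) and cell ids (colnames)")
  }
  if (anyDuplicated(rownames(m))) {
    abort(paste0("duplicate gene id: ", rownames(m)[duplicated(rownames(m))][1]))
  }
  if (anyDuplicated(colnames(m))) {
    abort(paste0("duplicate cell id: ", colnames(m)[duplicated(colnames(m))][1]))
  }
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  bad <- which(vals < 0 | vals != round(vals))
  if (length(bad)) {
    coord <- if (methods::is(m, "sparseMatrix")) {
      ij <- Matrix::which(m < 0 | m != round(m), arr.ind = TRUE)[1, ]
      ij
    } else {
      ij <- which(matrix(vals, nrow(m)) < 0 | matrix(vals, nrow(m)) != round(vals),
                  arr.ind = TRUE)[1, ]
      ij
    }
    abort(sprintf("counts must be non-negative integers; offending entry at gene '%s', cell '%s'",
                  rownames(m)[coord[1]], colnames(m)[coord[2]]))
  }
  invisible(m)
}

#' Filter genes and cells
#'
#' Applies the standard UMI preprocessing filters in a fixed order: first
#' genes detected (count > 0) in fewer than `min_cells_per_gene` cells are
#' removed, then cells expressing fewer than `min_genes_per_cell` of the
#' remaining genes are removed. Exactly one gene pass and one cell pass are
#' performed; removing cells can in principle leave a gene below threshold
#' again, and such genes are deliberately kept (re-apply the filter if a
#' fixed point is wanted).
#'
#' @param m Count matrix, genes x cells.
#' @param min_cells_per_gene Keep genes detected in at least this many cells.
#' @param min_genes_per_cell Keep cells expressing at least this many genes.
#' @return The filtered sub-matrix; values are never altered.
#' @export
filter_counts <- function(m, min_cells_per_gene = 3, min_genes_per_cell = 2000) {
  stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0)
  keep_g <- Matrix::rowSums(m > 0) >= min_cells_per_gene
  m2 <- m[keep_g, , drop = FALSE]
  keep_c <- Matrix::colSums(m2 > 0) >= min_genes_per_cell
  out <- m2[, keep_c, drop = FALSE]
  if (nrow(out) == 0 || ncol(out) == 0) {
    abort("empty matrix after filtering")
  }
  out
}

#' Median-of-library-size scaling
#'
#' Optional depth normalization: each cell's counts are scaled so its
#' library size equals the median library size. Off by default throughout
#' the pipeline; the core method operates on raw UMI counts.
#'
#' @param m Count matrix, genes x cells.
#' @return Scaled matrix (no longer integer-valued).
#' @export
normalize_libsize <- function(m) {
  lib <- Matrix::colSums(m)
  if (any(lib == 0)) abort("cannot scale cells with zero total counts")
  out <- m %*% Matrix::Diagonal(ncol(m), median(lib) / lib)
  dimnames(out) <- dimnames(m)
  out
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: writes either a 10X-style Matrix Market
#' directory or a dense TSV with gene rows and a cell-id header.
#'
#' @param m Count matrix, genes x cells, with dimnames.
#' @param path Output directory (`mtx_dir`) or file (`dense`).
#' @param format `"mtx_dir"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("mtx_dir", "dense")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble(gene = rownames(m)), file.path(path, "genes.tsv"),
                     col_names = FALSE)
    readr::write_tsv(tibble(barcode = colnames(m)), file.path(path, "barcodes.tsv"),
                     col_names = FALSE)
  } else {
    df <- as.data.frame(as.matrix(m))
    df <- cbind(gene_id = rownames(m), df)
    readr::write_tsv(as_tibble(df), path)
  }
  invisible(path)
}
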