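## Count-matrix containers for the bulk and single-nucleus stages.

#' Bulk gene-by-sample count matrix
#'
#' @param counts nonnegative integer matrix, genes x samples, with
#'   dimnames.
#' @param sample_meta data.frame with `sample_id`, `group`
#'   (Match/Mismatch/Control) and `region` (AMI/Border/Remote), one row per
#'   column of `counts`.
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_input("'counts' must have gene rownames and sample colnames")
  }
  if (any(counts < 0) || anyNA(counts)) stop_input("'counts' must be nonnegative")
  stopifnot(is.data.frame(sample_meta),
            all(c("sample_id", "group", "region") %in% names(sample_meta)))
  if (nrow(sample_meta) != ncol(counts) ||
      !identical(as.character(sample_meta$sample_id), colnames(counts))) {
    stop_input("'sample_meta$sample_id' must match count matrix columns")
  }
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$sample_meta$group, x$sample_meta$region))
  invisible(x)
}

#' Single-nucleus gene-by-cell count matrix
#'
#' Wraps a (sparse) counts matrix with per-cell metadata; `detected_genes`
#' and `mito_fraction` are always recomputed from the counts so the stored
#' metadata cannot drift from the matrix.
#'
#' @param counts nonnegative integer matrix or `Matrix::dgCMatrix`,
#'   genes x cells, with dimnames.
#' @param cell_meta data.frame with `cell_id` plus any annotation columns,
#'   one row per cell.
#' @param hashtag_counts optional cells x tags nonnegative matrix.
#' @param mito mitochondrial gene symbols used for `mito_fraction`.
#' @return object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta, hashtag_counts = NULL,
                        mito = mito_gene_list()) {
  if (!inherits(counts, "sparseMatrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) ||
      (is.null(colnames(counts)) && ncol(counts) > 0L)) {
    stop_input("'counts' must have gene rownames and cell colnames")
  }
  if (any(counts@x < 0)) stop_input("'counts' must be nonnegative")
  stopifnot(is.data.frame(cell_meta), "cell_id" %in% names(cell_meta))
  if (nrow(cell_meta) != ncol(counts) ||
      !identical(as.character(cell_meta$cell_id),
                 colnames(counts) %||% character(0))) {
    stop_input("'cell_meta$cell_id' must match count matrix columns")
  }
  cell_meta$detected_genes <- Matrix::colSums(counts > 0)
  tot <- Matrix::colSums(counts)
  mito_present <- intersect(mito, rownames(counts))
  msum <- if (length(mito_present)) {
    Matrix::colSums(counts[mito_present, , drop = FALSE])
  } else rep(0, ncol(counts))
  cell_meta$mito_fraction <- ifelse(tot > 0, msum / tot, 0)
  if (!is.null(hashtag_counts)) {
    hashtag_counts <- as.matrix(hashtag_counts)
    if (nrow(hashtag_counts) != ncol(counts)) {
      stop_input("'hashtag_counts' must have one row per cell")
    }
    if (any(hashtag_counts < 0)) stop_input("'hashtag_counts' must be nonnegative")
  }
  structure(list(counts = counts, cell_meta = cell_meta,
                 hashtag_counts = hashtag_counts),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$hashtag_counts)) {
    cat(sprintf(", %d hashtags", ncol(x$hashtag_counts)))
  }
  cat("\n")
  cat(sprintf("  median detected genes %d, median mito fraction %.3f\n",
              as.integer(median(x$cell_meta$detected_genes)),
              median(x$cell_meta$mito_fraction)))
  invisible(x)
}

## counts-per-10k then log1p (single-cell convention used by the annotation
## and DE stages)
log_norm_cells <- function(counts, scale = 1e4) {
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  sf <- scale / tot
  out <- counts %*% Matrix::Diagonal(x = sf)
  dimnames(out) <- dimnames(counts)
  log1p(out)
}

## counts-per-million then log1p for bulk samples
log_cpm <- function(counts) {
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  log1p(sweep(counts, 2, 1e6 / tot, `*`))
}
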