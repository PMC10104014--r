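#' Assemble a cell table
#'
#' A `cell_table` bundles a sparse cell-by-gene UMI count matrix with per-cell
#' and per-gene metadata. It is the input container for every pipeline stage.
#' Counts are stored as a [Matrix::dgCMatrix] with cells as rows; metadata are
#' tibbles aligned to the matrix dimnames.
#'
#' @param counts Sparse (or dense, coerced) non-negative integer matrix,
#'   cells x genes, with rownames (cell ids) and colnames (gene ids).
#' @param cell_meta Tibble/data frame with one row per cell. Must contain a
#'   `cell_id` column matching `rownames(counts)`; typical columns are
#'   `embryo_id`, `timepoint` (embryonic day), `somite_count`, `type_label`.
#'   QC columns `umi_total` and `gene_count` are (re)computed from the counts.
#' @param gene_meta Optional tibble with one row per gene and a `gene_id`
#'   column; other columns such as `biotype` or `is_tf` are carried along.
#'
#' @return An object of class `cell_table`: a list with elements `counts`,
#'   `cell_meta`, `gene_meta`.
#' @export
cell_table <- function(counts, cell_meta, gene_meta = NULL) {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts))) {
    stop("`counts` must carry cell rownames and gene colnames")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) stop("cell_meta needs a `cell_id` column")
  if (!setequal(cell_meta$cell_id, rownames(counts)) ||
      anyDuplicated(cell_meta$cell_id)) {
    stop("cell_meta$cell_id must match rownames(counts) one-to-one")
  }
  cell_meta <- cell_meta[match(rownames(counts), cell_meta$cell_id), ]
  if ("timepoint" %in% names(cell_meta) &&
      any(!is.finite(cell_meta$timepoint))) {
    stop("timepoint must be finite for every cell")
  }
  cell_meta$umi_total <- Matrix::rowSums(counts)
  cell_meta$gene_count <- Matrix::rowSums(counts > 0)
  if (is.null(gene_meta)) {
    gene_meta <- tibble::tibble(gene_id = colnames(counts))
  } else {
    gene_meta <- tibble::as_tibble(gene_meta)
    if (!"gene_id" %in% names(gene_meta)) stop("gene_meta needs a `gene_id` column")
    gene_meta <- gene_meta[match(colnames(counts), gene_meta$gene_id), ]
    if (anyNA(gene_meta$gene_id)) stop("gene_meta is missing some genes")
  }
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  if ("timepoint" %in% names(x$cell_meta)) {
    tp <- sort(unique(x$cell_meta$timepoint))
    cat(sprintf("  timepoints: %s\n",
                paste(format(tp, trim = TRUE), collapse = ", ")))
  }
  if ("type_label" %in% names(x$cell_meta)) {
    cat(sprintf("  %d type labels\n", dplyr::n_distinct(x$cell_meta$type_label)))
  }
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$counts)

#' Subset a cell table to a set of cells
#'
#' @param table A [cell_table].
#' @param cells Logical mask, integer indices, or character cell ids.
#' @return A [cell_table] restricted to those cells (gene set unchanged).
#' @export
filter_cells <- function(table, cells) {
  stopifnot(inherits(table, "cell_table"))
  if (is.character(cells)) cells <- match(cells, rownames(table$counts))
  cell_table(table$counts[cells, , drop = FALSE],
             table$cell_meta[cells, , drop = FALSE],
             table$gene_meta)
}

#' Write a cell table to MatrixMarket + TSV files
#'
#' Writes `matrix.mtx` (cells x genes counts), `cells.tsv` and `genes.tsv`
#' into `dir`. The inverse of [read_cell_table()].
#'
#' @param table A [cell_table].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cell_table <- function(table, dir) {
  stopifnot(inherits(table, "cell_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(table$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(table$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell table written by [write_cell_table()]
#'
#' @param dir Directory containing `matrix.mtx`, `cells.tsv`, `genes.tsv`.
#' @return A [cell_table].
#' @export
read_cell_table <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  rownames(m) <- cells$cell_id
  colnames(m) <- genes$gene_id
  cell_table(m, cells, genes)
}
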