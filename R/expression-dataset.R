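#' Construct an expression dataset
#'
#' The central container of the package: a sparse genes-by-cells matrix of
#' raw UMI counts plus per-cell metadata, an optional library-normalised
#' layer and an optional low-dimensional embedding. All pipeline stages take
#' and return this object; result tables are tibbles.
#'
#' @param counts genes-by-cells matrix of non-negative integer counts
#'   (dense or any `Matrix` class; stored as sparse `dgCMatrix`).
#' @param gene_ids,cell_ids character vectors naming rows/columns; default to
#'   the dimnames of `counts`.
#' @param cell_meta data frame keyed by `cell_id` with columns
#'   `cluster_label`, `condition`, `sample_id`, `dataset_id`. Missing columns
#'   (or a `NULL` table) are filled with the sentinel `"unassigned"`.
#' @param normalized optional matrix of non-negative reals, same shape and
#'   identifiers as `counts`.
#' @param embedding optional cells-by-d numeric matrix.
#'
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(counts, gene_ids = rownames(counts),
                               cell_ids = colnames(counts), cell_meta = NULL,
                               normalized = NULL, embedding = NULL) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    rlang::abort("`gene_ids` and `cell_ids` are required when `counts` has no dimnames.",
                 class = "anchortraj_validation_error")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids)) {
    rlang::abort(sprintf(
      "counts is %d x %d but %d gene ids and %d cell ids were supplied.",
      nrow(counts), ncol(counts), length(gene_ids), length(cell_ids)),
      class = "anchortraj_validation_error")
  }
  if (anyDuplicated(gene_ids)) {
    rlang::abort("duplicate gene ids.", class = "anchortraj_validation_error")
  }
  if (anyDuplicated(cell_ids)) {
    rlang::abort("duplicate cell barcodes.", class = "anchortraj_validation_error")
  }
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != round(counts@x)))) {
    bad <- which(counts@x < 0 | counts@x != round(counts@x))[1]
    rlang::abort(sprintf("counts must be non-negative integers (offending value %g).",
                         counts@x[bad]),
                 class = "anchortraj_format_error")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  cell_meta <- complete_cell_meta(cell_meta, cell_ids)
  if (!is.null(normalized)) {
    normalized <- methods::as(Matrix::Matrix(normalized, sparse = TRUE), "CsparseMatrix")
    if (!identical(dim(normalized), dim(counts))) {
      rlang::abort("normalized layer must have the same shape as counts.",
                   class = "anchortraj_validation_error")
    }
    dimnames(normalized) <- dimnames(counts)
  }
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != length(cell_ids)) {
      rlang::abort("embedding must have one row per cell.",
                   class = "anchortraj_validation_error")
    }
    rownames(embedding) <- cell_ids
  }
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta, normalized = normalized,
                 embedding = embedding),
            class = "expression_dataset")
}

meta_columns <- c("cluster_label", "condition", "sample_id", "dataset_id")

complete_cell_meta <- function(cell_meta, cell_ids) {
  if (is.null(cell_meta)) {
    cell_meta <- tibble::tibble(cell_id = cell_ids)
  }
  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    rlang::abort("cell_meta must contain a cell_id column.",
                 class = "anchortraj_validation_error")
  }
  cell_meta$cell_id <- as.character(cell_meta$cell_id)
  if (anyDuplicated(cell_meta$cell_id)) {
    rlang::abort("cell_meta has duplicated cell ids.",
                 class = "anchortraj_validation_error")
  }
  missing <- setdiff(cell_ids, cell_meta$cell_id)
  if (length(missing)) {
    rlang::abort(sprintf("cell_meta is missing %d cells (first: %s).",
                         length(missing), missing[1]),
                 class = "anchortraj_validation_error")
  }
  for (col in meta_columns) {
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- "unassigned"
    cell_meta[[col]] <- as.character(cell_meta[[col]])
  }
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id),
                         c("cell_id", meta_columns,
                           setdiff(names(cell_meta), c("cell_id", meta_columns)))]
  cell_meta
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  clusters: %s\n",
              paste(utils::head(sort(unique(x$cell_meta$cluster_label)), 8), collapse = ", ")))
  cat(sprintf("  layers: counts%s%s\n",
              if (!is.null(x$normalized)) ", normalized" else "",
              if (!is.null(x$embedding)) sprintf("; embedding (%dd)", ncol(x$embedding)) else ""))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$counts)

#' Subset an expression dataset by genes and/or cells
#'
#' @param dataset an [expression_dataset()].
#' @param genes,cells character identifiers (or logical/integer indices) to
#'   keep; `NULL` keeps everything. Order of the supplied ids is preserved.
#' @return A new `expression_dataset`.
#' @export
subset_dataset <- function(dataset, genes = NULL, cells = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  gi <- if (is.null(genes)) dataset$gene_ids else genes
  ci <- if (is.null(cells)) dataset$cell_ids else cells
  if (is.character(gi)) {
    bad <- setdiff(gi, dataset$gene_ids)
    if (length(bad)) rlang::abort(sprintf("unknown gene id: %s", bad[1]),
                                  class = "anchortraj_validation_error")
  } else gi <- dataset$gene_ids[gi]
  if (is.character(ci)) {
    bad <- setdiff(ci, dataset$cell_ids)
    if (length(bad)) rlang::abort(sprintf("unknown cell id: %s", bad[1]),
                                  class = "anchortraj_validation_error")
  } else ci <- dataset$cell_ids[ci]
  expression_dataset(
    counts = dataset$counts[gi, ci, drop = FALSE],
    gene_ids = gi, cell_ids = ci,
    cell_meta = dataset$cell_meta[match(ci, dataset$cell_meta$cell_id), , drop = FALSE],
    normalized = if (!is.null(dataset$normalized)) dataset$normalized[gi, ci, drop = FALSE],
    embedding = if (!is.null(dataset$embedding)) dataset$embedding[ci, , drop = FALSE])
}

# Internal: dense normalized submatrix (genes x cells), erroring when the
# layer is absent. Rank statistics downstream always state the layer used.
normalized_matrix <- function(dataset, genes = NULL, cells = NULL) {
  if (is.null(dataset$normalized)) {
    rlang::abort("dataset has no normalized layer; run normalize_log() first.",
                 class = "anchortraj_validation_error")
  }
  m <- dataset$normalized
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  as.matrix(m)
}
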