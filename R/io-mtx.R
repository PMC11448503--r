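#' Read a 10x-style MatrixMarket count bundle
#'
#' Reads `matrix.mtx` + `features.tsv` + `barcodes.tsv` (plus an optional
#' cell-metadata TSV) into an [expression_dataset()]. Orientation on disk
#' varies between exports; genes are returned as rows regardless, inferred by
#' matching the matrix dimensions against the features/barcodes lengths.
#' A square matrix whose two dimensions both match is ambiguous and rejected.
#'
#' @param matrix_path MatrixMarket coordinate file with integer values.
#' @param features_path TSV, one gene per line; only the first column is used
#'   (Cell Ranger writes id/symbol/type, plain exports a single column).
#' @param barcodes_path one barcode per line.
#' @param meta_path optional TSV with header containing at least `cell_id`
#'   and `cluster_label`; absent metadata columns are filled with
#'   `"unassigned"`.
#' @return An `expression_dataset`.
#' @export
read_mtx_bundle <- function(matrix_path, features_path, barcodes_path,
                            meta_path = NULL) {
  genes <- read_first_column(features_path)
  barcodes <- read_first_column(barcodes_path)
  m <- Matrix::readMM(matrix_path)
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x)))) {
    tm <- methods::as(m, "TsparseMatrix")
    bad <- which(tm@x < 0 | tm@x != round(tm@x))[1]
    rlang::abort(sprintf(
      "matrix values must be non-negative integers; entry (%d, %d) is %g.",
      tm@i[bad] + 1L, tm@j[bad] + 1L, tm@x[bad]),
      class = "anchortraj_format_error")
  }
  ng <- length(genes); nc <- length(barcodes)
  rows_are_genes <- nrow(m) == ng && ncol(m) == nc
  rows_are_cells <- nrow(m) == nc && ncol(m) == ng
  if (rows_are_genes && rows_are_cells && ng != nc) rows_are_cells <- FALSE
  if (rows_are_genes && rows_are_cells) {
    rlang::abort(sprintf(
      "square %d x %d matrix with equal features/barcodes counts: orientation is ambiguous.",
      nrow(m), ncol(m)),
      class = "anchortraj_format_error")
  }
  if (!rows_are_genes && !rows_are_cells) {
    rlang::abort(sprintf(
      "matrix is %d x %d but features has %d lines and barcodes has %d lines.",
      nrow(m), ncol(m), ng, nc),
      class = "anchortraj_format_error")
  }
  if (rows_are_cells) m <- Matrix::t(m)
  meta <- if (!is.null(meta_path)) read_cell_meta(meta_path) else NULL
  expression_dataset(m, gene_ids = genes, cell_ids = barcodes, cell_meta = meta)
}

read_first_column <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sub("\t.*$", "", lines)
}

read_cell_meta <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  need <- c("cell_id", "cluster_label")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    rlang::abort(sprintf("cell metadata is missing required column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "anchortraj_format_error")
  }
  meta
}

#' Write an expression dataset as a MatrixMarket bundle
#'
#' Writes `matrix.mtx` (coordinate integer, genes as rows), `features.tsv`,
#' `barcodes.tsv` and `cell_meta.tsv` so that
#' `read_mtx_bundle(write_mtx_bundle(d))` round-trips exactly.
#'
#' @param dataset an [expression_dataset()].
#' @param out_dir output directory, created if needed.
#' @return Named character vector of the four file paths, invisibly usable in
#'   pipelines.
#' @export
write_mtx_bundle <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (ncol(dataset$counts) == 0L || nrow(dataset$counts) == 0L) {
    rlang::abort("refusing to serialize an empty dataset (0 genes or 0 cells).",
                 class = "anchortraj_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(sprintf("cannot create output directory %s", out_dir),
                 class = "anchortraj_io_error")
  }
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             features = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             meta = file.path(out_dir, "cell_meta.tsv"))
  tm <- methods::as(dataset$counts, "TsparseMatrix")
  ord <- order(tm@j, tm@i)
  header <- c("%%MatrixMarket matrix coordinate integer general",
              sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x)))
  body <- sprintf("%d %d %d", tm@i[ord] + 1L, tm@j[ord] + 1L, as.integer(tm@x[ord]))
  writeLines(c(header, body), paths[["matrix"]])
  writeLines(dataset$gene_ids, paths[["features"]])
  writeLines(dataset$cell_ids, paths[["barcodes"]])
  readr::write_tsv(dataset$cell_meta, paths[["meta"]], progress = FALSE)
  invisible(paths)
}
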