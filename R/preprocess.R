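#' Quality-control thresholds
#'
#' Defaults follow the standard droplet-QC rules used throughout the
#' pipeline: keep cells with >= 200 detected genes, >= 500 UMI,
#' log10(genes)/log10(UMI) > 0.8 and mitochondrial fraction < 30%, after
#' removing genes seen in fewer than 3 cells. Mitochondrial genes are
#' identified by a case-insensitive id prefix so both mouse (`mt-`) and
#' human (`MT-`) symbol dialects are caught.
#'
#' @param min_genes_per_cell,min_umi_per_cell,min_log10_genes_per_umi,max_mito_fraction,min_cells_per_gene,mito_prefix
#'   see description.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 200L, min_umi_per_cell = 500L,
                          min_log10_genes_per_umi = 0.8,
                          max_mito_fraction = 0.30, min_cells_per_gene = 3L,
                          mito_prefix = "mt-") {
  stopifnot(min_genes_per_cell >= 0, min_umi_per_cell >= 0,
            min_log10_genes_per_umi >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_cells_per_gene >= 0)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_umi_per_cell = min_umi_per_cell,
                 min_log10_genes_per_umi = min_log10_genes_per_umi,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Quality-control filtering of cells and genes
#'
#' Applies the gene filter (expressed in >= `min_cells_per_gene` cells)
#' first, then the four cell filters, with
#' `log10GenesPerUMI = log10(genes detected) / log10(total UMI)`. The order
#' of surviving gene and cell ids is preserved. The report records
#' per-criterion removal counts for both filter orders, since criteria can
#' overlap.
#'
#' @param dataset an [expression_dataset()] holding raw integer counts.
#' @param thresholds a [qc_thresholds()] list.
#' @return A list with elements `dataset` (the filtered
#'   `expression_dataset`) and `report` (a `qc_report`).
#' @export
qc_filter <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  th <- thresholds
  counts <- dataset$counts

  cell_fail <- function(m) {
    umi <- Matrix::colSums(m)
    genes_det <- Matrix::colSums(m > 0)
    ratio <- ifelse(umi > 1, log10(pmax(genes_det, 1)) / log10(umi), 0)
    mito_genes <- startsWith(tolower(rownames(m)), tolower(th$mito_prefix))
    mito_frac <- if (any(mito_genes)) {
      ifelse(umi > 0, Matrix::colSums(m[mito_genes, , drop = FALSE]) / umi, 0)
    } else rep(0, ncol(m))
    list(genes = genes_det < th$min_genes_per_cell,
         umi = umi < th$min_umi_per_cell,
         ratio = ratio <= th$min_log10_genes_per_umi,
         mito = mito_frac >= th$max_mito_fraction)
  }

  # gene filter first, then cell filters, iterated to a fixed point so the
  # result is idempotent (removing cells can drop a gene below the floor)
  keep_gene <- rep(TRUE, nrow(counts))
  keep_cell <- rep(TRUE, ncol(counts))
  fail <- NULL
  repeat {
    prev <- c(keep_gene, keep_cell)
    kept_cells <- counts[, keep_cell, drop = FALSE]
    keep_gene <- Matrix::rowSums(kept_cells > 0) >= th$min_cells_per_gene
    fail <- cell_fail(counts[keep_gene, , drop = FALSE])
    keep_cell <- !(fail$genes | fail$umi | fail$ratio | fail$mito)
    if (!any(keep_cell)) {
      rlang::abort("empty after QC: no cell passes all filters.",
                   class = "anchortraj_validation_error")
    }
    if (identical(prev, c(keep_gene, keep_cell))) break
  }
  fail_cf <- cell_fail(counts)  # cell-filter-first counts, for the report

  out <- subset_dataset(dataset,
                        genes = dataset$gene_ids[keep_gene],
                        cells = dataset$cell_ids[keep_cell])
  report <- structure(list(
    thresholds = th,
    n_genes_in = nrow(counts), n_cells_in = ncol(counts),
    n_genes_out = nrow(out$counts), n_cells_out = ncol(out$counts),
    removed = tibble::tibble(
      criterion = c("gene_min_cells", "cell_min_genes", "cell_min_umi",
                    "cell_log10_genes_per_umi", "cell_mito_fraction"),
      removed_gene_filter_first = c(sum(!keep_gene), sum(fail$genes),
                                    sum(fail$umi), sum(fail$ratio), sum(fail$mito)),
      removed_cell_filter_first = c(sum(!keep_gene), sum(fail_cf$genes),
                                    sum(fail_cf$umi), sum(fail_cf$ratio),
                                    sum(fail_cf$mito)))),
    class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d genes, %d/%d cells retained\n",
              x$n_genes_out, x$n_genes_in, x$n_cells_out, x$n_cells_in))
  print(x$removed)
  invisible(x)
}

#' Library-size log-normalisation
#'
#' Fills the `normalized` layer with
#' `ln(1 + scale * counts[g, c] / total_umi[c])`.
#'
#' @param dataset an [expression_dataset()] with raw counts.
#' @param scale size factor target (default `1e4`).
#' @return The dataset with a `normalized` layer.
#' @export
normalize_log <- function(dataset, scale = 1e4) {
  stopifnot(inherits(dataset, "expression_dataset"))
  umi <- Matrix::colSums(dataset$counts)
  if (any(umi == 0)) {
    rlang::abort(sprintf("cell %s has zero total UMI; run qc_filter() first.",
                         dataset$cell_ids[which(umi == 0)[1]]),
                 class = "anchortraj_validation_error")
  }
  norm <- dataset$counts
  norm@x <- log1p(scale * norm@x / rep.int(umi, diff(norm@p)))
  dataset$normalized <- norm
  dataset
}

#' Highly variable gene selection
#'
#' Ranks genes by binned normalised dispersion: dispersion = variance/mean
#' of the normalized layer, z-scored within 20 equal-count bins of gene
#' mean. Zero-variance genes rank last; remaining ties break by gene id.
#'
#' @param dataset dataset with a normalized layer.
#' @param n_hvgs number of genes to return.
#' @return Character vector of `n_hvgs` gene ids, most variable first.
#' @export
select_hvgs <- function(dataset, n_hvgs) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (n_hvgs > length(dataset$gene_ids)) {
    rlang::abort("n_hvgs exceeds the number of genes.",
                 class = "anchortraj_validation_error")
  }
  m <- dataset$normalized
  if (is.null(m)) rlang::abort("normalized layer required.",
                               class = "anchortraj_validation_error")
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  v <- pmax(0, (ex2 - mu^2) * ncol(m) / max(1, ncol(m) - 1))
  disp <- ifelse(mu > 0, v / mu, 0)
  stats <- tibble::tibble(gene = dataset$gene_ids, mu = mu, v = v, disp = disp) |>
    dplyr::mutate(bin = dplyr::ntile(.data$mu, 20)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(z = if (dplyr::n() > 1 && stats::sd(.data$disp) > 0) {
      (.data$disp - mean(.data$disp)) / stats::sd(.data$disp)
    } else 0) |>
    dplyr::ungroup() |>
    dplyr::mutate(z = ifelse(.data$v == 0, -Inf, .data$z)) |>
    dplyr::arrange(dplyr::desc(.data$z), .data$gene)
  stats$gene[seq_len(n_hvgs)]
}

#' Principal component embedding
#'
#' Per-gene centred (unscaled) PCA of cells over a chosen gene panel, with a
#' deterministic sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param dataset dataset with a normalized layer.
#' @param genes character vector of genes to use.
#' @param n_components number of components (default 8).
#' @return List with `embedding` (cells x k), `loadings` (genes x k),
#'   `explained_variance` (length k), and `center` (per-gene means).
#' @export
pca_embed <- function(dataset, genes, n_components = 8) {
  stopifnot(inherits(dataset, "expression_dataset"))
  bad <- setdiff(genes, dataset$gene_ids)
  if (length(bad)) rlang::abort(sprintf("unknown gene: %s", bad[1]),
                                class = "anchortraj_validation_error")
  if (n_components > min(length(dataset$cell_ids), length(genes))) {
    rlang::abort("n_components exceeds min(n_cells, n_genes).",
                 class = "anchortraj_validation_error")
  }
  x <- t(normalized_matrix(dataset, genes = genes))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  emb <- sweep(pc$x, 2, flip, `*`)
  rownames(emb) <- dataset$cell_ids
  list(embedding = emb, loadings = rot,
       explained_variance = pc$sdev[seq_len(n_components)]^2,
       center = pc$center)
}
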