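#' Expressing-cell enrichment in a target cluster
#'
#' "Expressing" means raw UMI count strictly above `threshold` (default 0,
#' the conventional nonzero definition). With `N` cells in total, `K`
#' expressing cells overall, `n` cells in the target cluster and `k`
#' expressing cells in the target cluster, the enrichment p-value is the
#' one-tailed upper hypergeometric `P(X >= k)`.
#'
#' @param dataset an [expression_dataset()].
#' @param gene gene id.
#' @param target_cluster cluster to test for enrichment.
#' @param threshold count threshold defining "expressing".
#' @return List with `stats` (tibble: cluster, n_cells, n_expressing,
#'   fraction; one row per cluster) and `test` (test-result tibble).
#' @export
expressing_cell_enrichment <- function(dataset, gene, target_cluster,
                                       threshold = 0) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!gene %in% dataset$gene_ids) {
    rlang::abort(sprintf("gene %s absent from dataset.", gene),
                 class = "anchortraj_validation_error")
  }
  labels <- dataset$cell_meta$cluster_label
  if (!target_cluster %in% labels) {
    rlang::abort(sprintf("cluster %s absent from dataset.", target_cluster),
                 class = "anchortraj_validation_error")
  }
  expressing <- as.vector(dataset$counts[gene, ] > threshold)
  stats_tbl <- tibble::tibble(cluster = labels, expressing = expressing) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_expressing = sum(.data$expressing),
                     fraction = mean(.data$expressing), .groups = "drop")
  N <- length(expressing)
  K <- sum(expressing)
  n <- sum(labels == target_cluster)
  k <- sum(expressing & labels == target_cluster)
  list(stats = stats_tbl, test = hypergeom_upper(k, K, n, N),
       gene = gene, target_cluster = target_cluster, threshold = threshold)
}

#' Expression-level group test for a target cluster
#'
#' Two-sided Mann-Whitney test of normalized expression, target cluster
#' versus all other cells.
#'
#' @inheritParams expressing_cell_enrichment
#' @return One-row test-result tibble.
#' @export
expression_group_test <- function(dataset, gene, target_cluster) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!gene %in% dataset$gene_ids) {
    rlang::abort(sprintf("gene %s absent from dataset.", gene),
                 class = "anchortraj_validation_error")
  }
  labels <- dataset$cell_meta$cluster_label
  expr <- drop(normalized_matrix(dataset, genes = gene))
  inside <- labels == target_cluster
  if (!any(inside) || all(inside)) {
    rlang::abort("both groups must be nonempty.",
                 class = "anchortraj_validation_error")
  }
  mann_whitney(expr[inside], expr[!inside])
}
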