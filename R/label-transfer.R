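#' Transfer reference cluster labels to a query dataset
#'
#' A deterministic k-nearest-neighbour classifier in reference PCA space:
#' highly variable genes are chosen on the reference restricted to shared
#' genes, both datasets are standardised by the reference per-gene
#' mean/sd, the query is projected onto the reference PCA loadings, and
#' each query cell takes the majority label of its `k` nearest reference
#' cells (Euclidean distance in PC space), with ties broken by summed
#' inverse distance. The score is the winning vote fraction.
#'
#' @param reference [expression_dataset()] with cluster labels (normalized
#'   layer computed on demand).
#' @param query [expression_dataset()] sharing >= 500 gene ids with the
#'   reference.
#' @param k neighbours per query cell.
#' @param n_pcs number of principal components.
#' @param n_hvgs highly variable genes selected on the reference.
#' @return A `label_transfer_result` tibble with columns `cell_id`,
#'   `predicted_label`, `score`, and the parameters as attributes.
#' @export
transfer_labels <- function(reference, query, k = 15, n_pcs = 30,
                            n_hvgs = 2000) {
  stopifnot(inherits(reference, "expression_dataset"),
            inherits(query, "expression_dataset"))
  shared <- intersect(reference$gene_ids, query$gene_ids)
  if (length(shared) < 500) {
    rlang::abort(sprintf("only %d shared genes between datasets (need >= 500).",
                         length(shared)),
                 class = "anchortraj_validation_error")
  }
  if (k > length(reference$cell_ids)) {
    rlang::abort("k exceeds the number of reference cells.",
                 class = "anchortraj_validation_error")
  }
  if (is.null(reference$normalized)) reference <- normalize_log(reference)
  if (is.null(query$normalized)) query <- normalize_log(query)

  ref_shared <- subset_dataset(reference, genes = shared)
  n_hvgs <- min(n_hvgs, length(shared))
  hvgs <- select_hvgs(ref_shared, n_hvgs)
  n_pcs <- min(n_pcs, length(hvgs), length(reference$cell_ids))

  xr <- t(normalized_matrix(reference, genes = hvgs))
  ctr <- colMeans(xr)
  sds <- apply(xr, 2, stats::sd)
  sds[sds == 0] <- 1
  xr <- scale(xr, center = ctr, scale = sds)
  pc <- stats::prcomp(xr, center = FALSE, scale. = FALSE, rank. = n_pcs)
  ref_pc <- pc$x
  xq <- scale(t(normalized_matrix(query, genes = hvgs)), center = ctr, scale = sds)
  query_pc <- xq %*% pc$rotation

  labels <- reference$cell_meta$cluster_label
  # squared distances via the expansion trick; one row per query cell
  ref_sq <- rowSums(ref_pc^2)
  res <- purrr::map_dfr(seq_len(nrow(query_pc)), function(i) {
    d2 <- pmax(0, ref_sq - 2 * drop(ref_pc %*% query_pc[i, ]) + sum(query_pc[i, ]^2))
    nn <- order(d2)[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      invd <- vapply(top, function(lb) {
        sum(1 / (sqrt(d2[nn][labels[nn] == lb]) + 1e-10))
      }, 0)
      top <- top[which.max(invd)]
    }
    tibble::tibble(cell_id = query$cell_ids[i], predicted_label = top[1],
                   score = as.numeric(max(votes)) / k)
  })
  structure(res, class = c("label_transfer_result", class(res)),
            params = list(k = k, n_pcs = n_pcs, n_hvgs = n_hvgs,
                          shared_genes = length(shared)))
}
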