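#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a lineage model into a long pseudotime table
#' @param x a `lineage_model` with pseudotime computed.
#' @param ... unused.
#' @return Tibble with `cell_id`, `lineage`, `terminus`, `pseudotime`.
#' @export
tidy.lineage_model <- function(x, ...) {
  if (is.null(x$pseudotime)) {
    rlang::abort("pseudotime not computed yet.",
                 class = "anchortraj_validation_error")
  }
  termini <- colnames(x$pseudotime)
  out <- tidyr::pivot_longer(
    tibble::as_tibble(x$pseudotime, rownames = "cell_id"),
    -"cell_id", names_to = "terminus", values_to = "pseudotime")
  out$lineage <- match(out$terminus, termini)
  out[!is.na(out$pseudotime), c("cell_id", "lineage", "terminus", "pseudotime")]
}

#' @export
glance.lineage_model <- function(x, ...) {
  tibble::tibble(origin = x$origin, n_lineages = length(x$lineages),
                 n_clusters = nrow(x$centroids),
                 n_assigned = if (is.null(x$pseudotime)) NA_integer_ else
                   sum(rowSums(!is.na(x$pseudotime)) > 0))
}

#' @export
tidy.pseudotime_fit <- function(x, ...) x$grid

#' @export
glance.pseudotime_fit <- function(x, ...) {
  tibble::tibble(p_association = x$p_association,
                 f_statistic = x$f_statistic, df = x$df, n = x$n)
}

#' @export
tidy.coexpression_module <- function(x, ...) x$table

#' @export
glance.coexpression_module <- function(x, ...) {
  tibble::tibble(anchor = x$anchor, dataset_id = x$dataset_id,
                 n_retained = nrow(x$table), n_candidates = nrow(x$candidates),
                 fdr_threshold = x$fdr_threshold,
                 n_cells = length(x$cells_used))
}

#' @export
tidy.anchor_trajectory_report <- function(x, ...) x$summary

#' @export
tidy.module_intersection <- function(x, ...) {
  tibble::tibble(gene = x$genes)
}

#' @export
glance.module_intersection <- function(x, ...) {
  tibble::tibble(anchor = x$anchor, size_a = x$size_a, size_b = x$size_b,
                 size_intersection = length(x$genes))
}

#' @export
tidy.condition_correlation_comparison <- function(x, ...) {
  purrr::imap_dfr(x$rho, function(v, cond) {
    tibble::tibble(condition = cond, gene = names(v) %||% seq_along(v),
                   rho = as.numeric(v))
  })
}

#' @export
glance.condition_correlation_comparison <- function(x, ...) x$ks

#' @export
tidy.network_edges <- function(x, ...) x$edges

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_genes_in = x$n_genes_in, n_genes_out = x$n_genes_out,
                 n_cells_in = x$n_cells_in, n_cells_out = x$n_cells_out)
}

#' @export
tidy.qc_report <- function(x, ...) x$removed

`%||%` <- rlang::`%||%`
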