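#' Plot a lineage model over the embedding
#'
#' Cells coloured by cluster with the piecewise-linear lineage curves
#' overlaid through the cluster centroids.
#'
#' @param object a `lineage_model`.
#' @param embedding cells-by-2 coordinate matrix.
#' @param cluster_labels per-cell labels.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lineage_model <- function(object, embedding, cluster_labels, ...) {
  emb <- tibble::tibble(x = embedding[, 1], y = embedding[, 2],
                        cluster = cluster_labels)
  paths <- purrr::imap_dfr(object$lineages, function(path, i) {
    ctr <- object$centroids[path, , drop = FALSE]
    tibble::tibble(x = ctr[, 1], y = ctr[, 2],
                   lineage = paste0("lineage ", i))
  })
  ggplot2::ggplot(emb, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster),
                        size = 0.4, alpha = 0.6) +
    ggplot2::geom_path(data = paths,
                       ggplot2::aes(group = .data$lineage,
                                    linetype = .data$lineage),
                       linewidth = 0.8) +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' Plot anchor expression against pseudotime per lineage
#'
#' @param object an `anchor_trajectory_report`.
#' @param ... unused.
#' @return A ggplot object showing the fitted spline per lineage.
#' @export
autoplot.anchor_trajectory_report <- function(object, ...) {
  grids <- purrr::imap_dfr(object$fits, function(fit, i) {
    g <- fit$grid
    g$terminus <- object$summary$terminus[i]
    g
  })
  ggplot2::ggplot(grids, ggplot2::aes(.data$pseudotime, .data$fitted,
                                      colour = .data$terminus)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(y = sprintf("%s (fitted normalized expression)",
                              object$anchor)) +
    ggplot2::theme_minimal()
}

#' Density plot of anchor-module correlations by condition
#'
#' @param object a `condition_correlation_comparison`.
#' @param ... unused.
#' @return A ggplot object with the KS p-value in the subtitle.
#' @export
autoplot.condition_correlation_comparison <- function(object, ...) {
  df <- tidy.condition_correlation_comparison(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$rho, fill = .data$condition)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = sprintf("Spearman rho with %s", object$anchor),
                  subtitle = sprintf("two-sided KS p = %.3g",
                                     object$ks$p_value)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a marker Jaccard matrix
#'
#' @param jaccard matrix from [jaccard_matrix()].
#' @return A ggplot tile heatmap.
#' @export
plot_jaccard <- function(jaccard) {
  df <- tibble::as_tibble(jaccard, rownames = "cluster_a") |>
    tidyr::pivot_longer(-"cluster_a", names_to = "cluster_b",
                        values_to = "jaccard")
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster_a, .data$cluster_b,
                                   fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
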