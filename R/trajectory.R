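#' Infer origin-rooted lineages over cluster centroids
#'
#' Builds the minimum spanning tree of the Euclidean distances between
#' per-cluster mean embedding coordinates and reports every tree path from
#' the origin cluster to a leaf as a lineage. Vertices are ordered
#' lexicographically by cluster name so tied trees resolve
#' deterministically.
#'
#' @param embedding cells-by-d numeric matrix.
#' @param cluster_labels character vector, one label per embedding row.
#' @param origin name of the origin cluster.
#' @return A `lineage_model`: origin, list of ordered cluster paths,
#'   centroid matrix, and (until [compute_pseudotime()] is run) empty
#'   pseudotime.
#' @export
infer_lineages <- function(embedding, cluster_labels, origin) {
  embedding <- as.matrix(embedding)
  stopifnot(nrow(embedding) == length(cluster_labels))
  clusters <- sort(unique(cluster_labels))
  if (!origin %in% clusters) {
    rlang::abort(sprintf("origin cluster %s absent from labels.", origin),
                 class = "anchortraj_validation_error")
  }
  if (length(clusters) < 2) {
    rlang::abort("need at least 2 clusters to infer lineages.",
                 class = "anchortraj_validation_error")
  }
  centroids <- do.call(rbind, lapply(clusters, function(cl) {
    colMeans(embedding[cluster_labels == cl, , drop = FALSE])
  }))
  rownames(centroids) <- clusters

  d <- as.matrix(stats::dist(centroids))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  tree <- igraph::mst(g, algorithm = "prim")
  leaves <- setdiff(names(which(igraph::degree(tree) == 1)), origin)
  paths <- igraph::shortest_paths(tree, from = origin, to = leaves,
                                  output = "vpath")$vpath
  lineages <- lapply(paths, function(p) names(p))
  lineages <- lineages[order(vapply(lineages, function(x) x[length(x)], ""))]

  structure(list(origin = origin, lineages = lineages, centroids = centroids,
                 mst_edges = igraph::as_edgelist(tree),
                 pseudotime = NULL, assignment = NULL),
            class = "lineage_model")
}

#' @export
print.lineage_model <- function(x, ...) {
  cat(sprintf("<lineage_model> origin: %s; %d lineage(s)\n",
              x$origin, length(x$lineages)))
  for (l in x$lineages) cat("  ", paste(l, collapse = " -> "), "\n")
  if (!is.null(x$pseudotime)) {
    cat(sprintf("  pseudotime: %d cells assigned\n",
                sum(rowSums(!is.na(x$pseudotime)) > 0)))
  }
  invisible(x)
}

# Project points orthogonally onto a polyline; returns arc-length positions.
# The terminal segment extends linearly beyond the last centroid so cells
# past the terminus keep distinct pseudotimes (no atom at the curve end);
# the start is clamped at the origin centroid so pseudotime stays >= 0.
project_on_polyline <- function(points, vertices) {
  nseg <- nrow(vertices) - 1
  seg_vec <- vertices[-1, , drop = FALSE] - vertices[-nrow(vertices), , drop = FALSE]
  seg_len <- sqrt(rowSums(seg_vec^2))
  cum_len <- c(0, cumsum(seg_len))
  best_pt <- rep(Inf, nrow(points))
  best_d2 <- rep(Inf, nrow(points))
  for (s in seq_len(nseg)) {
    a <- vertices[s, ]
    rel <- sweep(points, 2, a)
    tt <- drop(rel %*% seg_vec[s, ]) / seg_len[s]^2
    hi <- if (s == nseg) Inf else 1
    tt <- pmin(hi, pmax(0, tt))
    proj <- outer(tt, seg_vec[s, ])
    d2 <- rowSums((rel - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_pt[upd] <- cum_len[s] + tt[upd] * seg_len[s]
  }
  best_pt
}

#' Per-cell pseudotime along each lineage
#'
#' Each lineage's ordered centroids define a piecewise-linear curve; each
#' cell whose cluster lies on the lineage path is orthogonally projected
#' onto its nearest curve segment and pseudotime is the arc length from the
#' origin centroid to the projection. Cells in clusters shared by several
#' lineages receive one pseudotime per lineage.
#'
#' @param model a [infer_lineages()] result.
#' @param embedding,cluster_labels the coordinates and labels the model was
#'   built from.
#' @return The `lineage_model` with `pseudotime` (cells x lineages, `NA`
#'   for unassigned) and `assignment` filled.
#' @export
compute_pseudotime <- function(model, embedding, cluster_labels) {
  stopifnot(inherits(model, "lineage_model"))
  embedding <- as.matrix(embedding)
  if (is.null(model$lineages) || !length(model$lineages)) {
    rlang::abort("model has no lineages.", class = "anchortraj_validation_error")
  }
  cell_ids <- rownames(embedding)
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(nrow(embedding)))
  pt <- matrix(NA_real_, nrow(embedding), length(model$lineages),
               dimnames = list(cell_ids,
                               vapply(model$lineages, function(l) l[length(l)], "")))
  for (li in seq_along(model$lineages)) {
    path <- model$lineages[[li]]
    if (length(path) < 2) {
      rlang::abort("lineage with fewer than 2 clusters.",
                   class = "anchortraj_validation_error")
    }
    on_path <- cluster_labels %in% path
    pt[on_path, li] <- project_on_polyline(
      embedding[on_path, , drop = FALSE],
      model$centroids[path, , drop = FALSE])
  }
  model$pseudotime <- pt
  model$assignment <- apply(!is.na(pt), 1, which, simplify = FALSE)
  model
}

#' Spline fit of expression against pseudotime
#'
#' Least-squares fit of expression on a cubic B-spline basis of pseudotime
#' (`df` basis functions plus intercept, internal knots at quantiles), with
#' the association p-value from the F-test of the spline model against the
#' intercept-only model.
#'
#' @param pseudotime,expression numeric vectors over >= 20 cells.
#' @param df spline degrees of freedom (>= 3).
#' @param grid_size points of the fitted-curve grid.
#' @return A `pseudotime_fit`: list with `p_association`, `f_statistic`,
#'   `coefficients`, `grid` (tibble of pseudotime/fitted), `df`, `n`.
#' @export
fit_pseudotime_gam <- function(pseudotime, expression, df = 5,
                               grid_size = 100) {
  keep <- is.finite(pseudotime) & is.finite(expression)
  pseudotime <- pseudotime[keep]; expression <- expression[keep]
  n <- length(pseudotime)
  if (n < 20) rlang::abort("need >= 20 cells with defined pseudotime.",
                           class = "anchortraj_validation_error")
  if (df < 3) rlang::abort("df must be >= 3.",
                           class = "anchortraj_validation_error")
  if (n <= df + 1) rlang::abort("fewer cells than spline parameters.",
                                class = "anchortraj_validation_error")
  basis <- splines::bs(pseudotime, df = df)
  fit <- stats::lm(expression ~ basis)
  if (stats::var(expression) == 0) {
    fstat <- 0; p <- 1
  } else {
    fs <- suppressWarnings(summary(fit))$fstatistic
    if (is.null(fs)) { fstat <- 0; p <- 1 } else {
      fstat <- unname(fs[1])
      p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    }
  }
  grid <- seq(min(pseudotime), max(pseudotime), length.out = grid_size)
  gb <- stats::predict(basis, grid)
  fitted_grid <- drop(cbind(1, gb) %*% stats::coef(fit))
  structure(list(p_association = unname(p), f_statistic = fstat,
                 coefficients = stats::coef(fit),
                 grid = tibble::tibble(pseudotime = grid, fitted = fitted_grid),
                 df = df, n = n),
            class = "pseudotime_fit")
}

#' Anchor-gene association along every lineage
#'
#' Fits the anchor's normalized expression against pseudotime on every
#' lineage, BH-adjusts the association p-values across lineages, flags
#' lineages with `q < alpha` as anchor-associated, and reports the mean
#' fitted expression over cells in the terminal pseudotime decile.
#'
#' @param dataset [expression_dataset()] with a normalized layer.
#' @param model a [compute_pseudotime()]-filled `lineage_model`.
#' @param anchor_gene gene id to profile.
#' @param df spline degrees of freedom.
#' @param alpha BH-adjusted significance level for flagging.
#' @return An `anchor_trajectory_report`: list with `summary` (tibble:
#'   lineage, terminus, n_cells, p, q, terminal_mean, flagged) and `fits`
#'   (per-lineage `pseudotime_fit`s).
#' @export
anchor_trajectory_report <- function(dataset, model, anchor_gene, df = 5,
                                     alpha = 0.05) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(model, "lineage_model"))
  if (!anchor_gene %in% dataset$gene_ids) {
    rlang::abort(sprintf("anchor gene %s absent from dataset.", anchor_gene),
                 class = "anchortraj_validation_error")
  }
  if (is.null(model$pseudotime)) {
    rlang::abort("run compute_pseudotime() before the anchor report.",
                 class = "anchortraj_validation_error")
  }
  expr <- drop(normalized_matrix(dataset, genes = anchor_gene))
  fits <- list()
  rows <- purrr::map_dfr(seq_along(model$lineages), function(li) {
    pt <- model$pseudotime[dataset$cell_ids, li]
    keep <- !is.na(pt)
    fit <- fit_pseudotime_gam(pt[keep], expr[keep], df = df)
    fits[[li]] <<- fit
    top <- pt[keep] >= stats::quantile(pt[keep], 0.9)
    fitted_cells <- stats::predict(
      stats::lm(expr[keep] ~ splines::bs(pt[keep], df = df)))
    tibble::tibble(
      lineage = li,
      terminus = model$lineages[[li]][length(model$lineages[[li]])],
      n_cells = sum(keep), p = fit$p_association,
      terminal_mean = mean(fitted_cells[top]))
  })
  rows$q <- bh_fdr(rows$p)
  rows$flagged <- rows$q < alpha
  structure(list(summary = rows, fits = fits, anchor = anchor_gene,
                 alpha = alpha),
            class = "anchor_trajectory_report")
}
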