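#' Per-cluster rank-sum marker table
#'
#' For each cluster, every gene detected in at least 10% of either group is
#' tested with a two-sided Mann-Whitney rank-sum of normalized expression
#' (cluster vs all other cells, normal approximation with tie and
#' continuity correction, vectorised over genes).
#' `log2fc = log2((mean_in + 1) / (mean_out + 1))` on the linear scale
#' `expm1(normalized)`; `pct_in`/`pct_out` are detection fractions; BH
#' adjustment is applied within each cluster's family of tested genes.
#'
#' @param dataset an [expression_dataset()] with a normalized layer and
#'   cluster labels.
#' @param min_detect_frac detection fraction defining testable genes.
#' @return A tibble with columns `cluster`, `gene`, `log2fc`, `p`, `q`,
#'   `pct_in`, `pct_out`.
#' @export
rank_sum_markers <- function(dataset, min_detect_frac = 0.10) {
  stopifnot(inherits(dataset, "expression_dataset"))
  labels <- dataset$cell_meta$cluster_label
  sizes <- table(labels)
  if (any(sizes < 3)) {
    rlang::abort(sprintf("cluster %s has fewer than 3 cells.",
                         names(sizes)[which(sizes < 3)[1]]),
                 class = "anchortraj_validation_error")
  }
  m <- normalized_matrix(dataset)
  n <- ncol(m)
  # mid-ranks of each gene across all cells, shared by every cluster contrast
  r <- matrix(0, nrow(m), n, dimnames = dimnames(m))
  tie_term <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) {
    r[g, ] <- rank(m[g, ])
    tl <- table(m[g, ])
    tie_term[g] <- sum(tl^3 - tl)
  }
  detected <- m > 0
  lin <- expm1(m)

  purrr::map_dfr(sort(unique(labels)), function(cl) {
    inside <- labels == cl
    n1 <- sum(inside); n2 <- n - n1
    pct_in <- rowMeans(detected[, inside, drop = FALSE])
    pct_out <- rowMeans(detected[, !inside, drop = FALSE])
    testable <- pct_in >= min_detect_frac | pct_out >= min_detect_frac
    if (!any(testable)) return(NULL)
    rsum <- rowSums(r[testable, inside, drop = FALSE])
    u <- rsum - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term[testable] / (n * (n - 1)))
    z <- ifelse(sigma2 > 0,
                (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2), 0)
    p <- pmin(1, 2 * stats::pnorm(-abs(z)))
    log2fc <- log2((rowMeans(lin[testable, inside, drop = FALSE]) + 1) /
                   (rowMeans(lin[testable, !inside, drop = FALSE]) + 1))
    tibble::tibble(cluster = cl, gene = rownames(m)[testable],
                   log2fc = unname(log2fc), p = unname(p), q = bh_fdr(unname(p)),
                   pct_in = unname(pct_in[testable]),
                   pct_out = unname(pct_out[testable]))
  })
}

#' Select cluster markers by the percentile fold-change rule
#'
#' Within each cluster, restricts to significantly upregulated genes
#' (`log2fc > 0`, `q < q_threshold`), takes the empirical `fc_quantile`
#' quantile of their log2 fold changes (linear interpolation between order
#' statistics) as a cutoff, and keeps genes strictly above the cutoff whose
#' in-cluster detection fraction is at least `min_prop`.
#'
#' @param marker_table output of [rank_sum_markers()].
#' @param fc_quantile fold-change percentile cutoff (default 0.85).
#' @param min_prop minimum in-cluster detection fraction (default 0.40).
#' @param q_threshold significance gate applied before the quantile step.
#' @return A `marker_sets` object: named list of marker gene vectors
#'   (ordered by decreasing log2fc) with the parameters attached.
#' @export
select_markers <- function(marker_table, fc_quantile = 0.85, min_prop = 0.40,
                           q_threshold = 0.05) {
  stopifnot(is.data.frame(marker_table))
  clusters <- sort(unique(marker_table$cluster))
  sets <- lapply(clusters, function(cl) {
    tab <- marker_table[marker_table$cluster == cl, ]
    up <- tab[tab$log2fc > 0 & tab$q < q_threshold, ]
    if (!nrow(up)) {
      rlang::warn(sprintf("cluster %s has no upregulated significant genes; empty marker set.", cl))
      return(character())
    }
    cutoff <- stats::quantile(up$log2fc, fc_quantile, type = 7, names = FALSE)
    keep <- up[up$log2fc > cutoff & up$pct_in >= min_prop, ]
    if (!nrow(keep)) {
      rlang::warn(sprintf("cluster %s retains no markers after the proportion filter.", cl))
      return(character())
    }
    keep$gene[order(-keep$log2fc, keep$gene)]
  })
  structure(stats::setNames(sets, clusters), class = "marker_sets",
            params = list(fc_quantile = fc_quantile, min_prop = min_prop,
                          q_threshold = q_threshold))
}

#' Jaccard similarity matrix between marker sets
#'
#' `J(A, B) = |A ∩ B| / |A ∪ B|`; the similarity of two empty
#' sets is defined as 0 (with a warning).
#'
#' @param marker_sets_a,marker_sets_b named lists of gene vectors
#'   ([select_markers()] output); `marker_sets_b` defaults to
#'   `marker_sets_a` for a symmetric matrix.
#' @return Numeric matrix of Jaccard indices in `[0, 1]`.
#' @export
jaccard_matrix <- function(marker_sets_a, marker_sets_b = marker_sets_a) {
  a <- unclass(marker_sets_a); b <- unclass(marker_sets_b)
  out <- matrix(0, length(a), length(b), dimnames = list(names(a), names(b)))
  warned <- FALSE
  for (i in seq_along(a)) for (j in seq_along(b)) {
    un <- length(union(a[[i]], b[[j]]))
    if (un == 0) {
      if (!warned) {
        rlang::warn("Jaccard of two empty marker sets defined as 0.")
        warned <- TRUE
      }
      out[i, j] <- 0
    } else {
      out[i, j] <- length(intersect(a[[i]], b[[j]])) / un
    }
  }
  out
}
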