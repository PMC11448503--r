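#' Pseudobulk aggregation of raw counts
#'
#' Sums raw counts over the selected cells within each level of a metadata
#' grouping column (default `sample_id`). Samples with no selected cells
#' are simply absent from the result.
#'
#' @param dataset an [expression_dataset()].
#' @param cells cell ids to aggregate (nonempty).
#' @param by metadata column to group by.
#' @return A samples-by-genes integer matrix with dimnames.
#' @export
pseudobulk_aggregate <- function(dataset, cells, by = "sample_id") {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!length(cells)) {
    rlang::abort("empty cell subset.", class = "anchortraj_validation_error")
  }
  bad <- setdiff(cells, dataset$cell_ids)
  if (length(bad)) rlang::abort(sprintf("unknown cell id: %s", bad[1]),
                                class = "anchortraj_validation_error")
  groups <- dataset$cell_meta[[by]][match(cells, dataset$cell_meta$cell_id)]
  if (any(is.na(groups))) {
    rlang::abort(sprintf("selected cells lack a %s value.", by),
                 class = "anchortraj_validation_error")
  }
  levs <- sort(unique(groups))
  ind <- Matrix::sparseMatrix(i = seq_along(cells),
                              j = match(groups, levs),
                              x = 1, dims = c(length(cells), length(levs)))
  pb <- Matrix::t(dataset$counts[, cells, drop = FALSE] %*% ind)
  out <- as.matrix(pb)
  dimnames(out) <- list(levs, dataset$gene_ids)
  out
}

#' Per-gene ranking statistic between two pseudobulk groups
#'
#' Welch t statistic of `log2(CPM + 1)` between two sample groups
#' (positive means higher in group A); genes with zero counts in every
#' sample are dropped. The resulting vector is the preranked-GSEA input.
#'
#' @param pseudobulk samples-by-genes matrix from
#'   [pseudobulk_aggregate()].
#' @param group_a_samples,group_b_samples row names, >= 2 each.
#' @return Tibble with columns `gene`, `stat`, sorted by decreasing
#'   `stat`.
#' @export
rank_genes <- function(pseudobulk, group_a_samples, group_b_samples) {
  if (length(group_a_samples) < 2 || length(group_b_samples) < 2) {
    rlang::abort("each group needs >= 2 samples.",
                 class = "anchortraj_validation_error")
  }
  missing <- setdiff(c(group_a_samples, group_b_samples), rownames(pseudobulk))
  if (length(missing)) {
    rlang::abort(sprintf("sample %s absent from pseudobulk.", missing[1]),
                 class = "anchortraj_validation_error")
  }
  keep <- colSums(pseudobulk) > 0
  pb <- pseudobulk[, keep, drop = FALSE]
  cpm <- log2(sweep(pb, 1, rowSums(pb), `/`) * 1e6 + 1)
  a <- cpm[group_a_samples, , drop = FALSE]
  b <- cpm[group_b_samples, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  se <- sqrt(va / na + vb / nb)
  stat <- ifelse(se > 0, (colMeans(a) - colMeans(b)) / se, 0)
  out <- tibble::tibble(gene = colnames(pb), stat = unname(stat))
  out[order(-out$stat, out$gene), ]
}

# ES of one gene set given sorted-rank hit positions.
# s_abs_w: |stat|^weight of the full ranking (decreasing stat order).
running_sum_es <- function(positions, s_abs_w, n_total) {
  k <- length(positions)
  pos <- sort(positions)
  w <- s_abs_w[pos]
  tot <- sum(w)
  miss_step <- 1 / (n_total - k)
  hit_cum <- if (tot > 0) cumsum(w) / tot else cumsum(rep(1 / k, k))
  top <- hit_cum - (pos - seq_len(k)) * miss_step          # just after each hit
  bottom <- c(0, hit_cum[-k]) - (pos - seq_len(k)) * miss_step  # just before
  max_dev <- max(0, top)
  min_dev <- min(0, bottom)
  # magnitude ties resolve to the positive deviation; the tolerance keeps
  # the choice stable across algebraically equivalent evaluation orders
  if (max_dev >= -min_dev - 1e-12) {
    list(es = max_dev, peak = if (max_dev > 0) pos[which.max(top)] else NA_integer_)
  } else {
    list(es = min_dev, peak = pos[which.min(bottom)])
  }
}

#' Preranked gene-set enrichment analysis
#'
#' Genes are sorted by decreasing statistic; the running sum adds
#' `|stat|^weight` (normalised by the set total) at set members and
#' subtracts `1/(N - N_hit)` elsewhere. ES is the signed maximum-magnitude
#' deviation. The null distribution comes from `n_perm` random same-size
#' gene sets (gene permutation); `NES = ES / mean(|null ES|)` over nulls of
#' matching sign and
#' `p = (1 + #{|null| >= |ES|, matching sign}) / (1 + #matching-sign nulls)`,
#' BH-adjusted across sets. The leading edge contains the set members at or
#' before the ES extremum (positive ES) or at/after it (negative ES).
#'
#' @param stat_vector named numeric vector of per-gene statistics (or a
#'   two-column gene/stat data frame as produced by [rank_genes()]).
#' @param gene_sets a [gene_set_collection()] or named list of gene
#'   vectors.
#' @param n_perm permutations (default `1e5`).
#' @param weight running-sum weight exponent (default 1).
#' @param seed integer seed for the permutation null.
#' @param min_size,max_size set-size filter after intersection with the
#'   ranked genes.
#' @return A `gsea_result` tibble: one row per set with `set`, `size`,
#'   `ES`, `NES`, `p`, `q`, `leading_edge` (list-column), `n_perm`,
#'   `seed`.
#' @export
gsea_preranked <- function(stat_vector, gene_sets, n_perm = 1e5, weight = 1,
                           seed = 1L, min_size = 5, max_size = 500) {
  if (is.data.frame(stat_vector)) {
    stat_vector <- stats::setNames(stat_vector$stat, stat_vector$gene)
  }
  if (is.null(names(stat_vector)) || anyDuplicated(names(stat_vector))) {
    rlang::abort("stat_vector must have unique gene names.",
                 class = "anchortraj_validation_error")
  }
  ord <- order(-stat_vector, names(stat_vector))
  stats_sorted <- stat_vector[ord]
  genes_ranked <- names(stats_sorted)
  n <- length(genes_ranked)
  s_abs_w <- abs(stats_sorted)^weight

  sets <- lapply(as_gene_set_list(gene_sets), intersect, genes_ranked)
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size & sizes < n]
  if (!length(sets)) {
    rlang::abort(sprintf("no gene set passes the size filter [%d, %d].",
                         min_size, max_size),
                 class = "anchortraj_validation_error")
  }

  obs <- lapply(sets, function(g) {
    running_sum_es(match(g, genes_ranked), s_abs_w, n)
  })

  res <- withr::with_seed(seed, {
    purrr::map_dfr(names(sets), function(nm) {
      k <- length(sets[[nm]])
      es <- obs[[nm]]$es
      null_es <- vapply(seq_len(n_perm), function(i) {
        running_sum_es(sample.int(n, k), s_abs_w, n)$es
      }, 0)
      matching <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      nes <- if (es == 0 || !length(matching)) 0 else es / mean(abs(matching))
      p <- (1 + sum(abs(matching) >= abs(es))) / (1 + length(matching))
      pos <- sort(match(sets[[nm]], genes_ranked))
      peak <- obs[[nm]]$peak
      le <- if (es > 0) genes_ranked[pos[pos <= peak]]
            else if (es < 0) genes_ranked[pos[pos >= peak]]
            else character()
      tibble::tibble(set = nm, size = k, ES = es, NES = nes, p = p,
                     leading_edge = list(le), n_perm = n_perm, seed = seed)
    })
  })
  res$q <- bh_fdr(res$p)
  res <- res[, c("set", "size", "ES", "NES", "p", "q", "leading_edge",
                 "n_perm", "seed")]
  class(res) <- c("gsea_result", class(res))
  res
}

#' Extract a leading-edge gene set from GSEA results
#'
#' @param gsea_results a [gsea_preranked()] result.
#' @param set_name set to extract.
#' @return A [gene_set_collection()] with one entry named
#'   `"<set>_leading_edge"`, writable via [write_gmt()].
#' @export
leading_edge_gene_set <- function(gsea_results, set_name) {
  stopifnot(inherits(gsea_results, "gsea_result"))
  row <- which(gsea_results$set == set_name)
  if (!length(row)) {
    rlang::abort(sprintf("set %s absent from GSEA results.", set_name),
                 class = "anchortraj_validation_error")
  }
  gene_set_collection(set = paste0(set_name, "_leading_edge"),
                      description = sprintf("leading edge of %s", set_name),
                      genes = gsea_results$leading_edge[row])
}

#' Binned-control signature score per cell
#'
#' All genes are split into `n_bins` equal-frequency bins by mean
#' normalized expression; for each signature gene, `n_ctrl` control genes
#' are sampled from its bin (excluding signature genes; with replacement
#' when the bin is smaller than `n_ctrl`). The per-cell score is the mean
#' normalized expression of the signature genes minus the mean over the
#' pooled control genes. `n_ctrl = NULL` uses every non-signature gene in
#' the bin exactly once.
#'
#' @param dataset [expression_dataset()] with a normalized layer.
#' @param gene_set character vector of signature genes (>= 1 present).
#' @param n_bins expression bins (default 24).
#' @param n_ctrl control genes per signature gene (default 100).
#' @param seed integer seed for control sampling.
#' @return A `module_score_result` tibble with `cell_id`, `score`.
#' @export
module_score <- function(dataset, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  present <- intersect(gene_set, dataset$gene_ids)
  if (!length(present)) {
    rlang::abort("no signature gene present in the dataset.",
                 class = "anchortraj_validation_error")
  }
  m <- dataset$normalized
  if (is.null(m)) rlang::abort("normalized layer required.",
                               class = "anchortraj_validation_error")
  mu <- Matrix::rowMeans(m)
  bins <- dplyr::ntile(rank(mu, ties.method = "first"),
                       min(n_bins, length(mu)))
  names(bins) <- dataset$gene_ids
  controls <- withr::with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- setdiff(names(bins)[bins == bins[g]], gene_set)
      if (!length(pool)) return(character())
      if (is.null(n_ctrl)) pool
      else sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  set_mean <- Matrix::colMeans(m[present, , drop = FALSE])
  ctrl_mean <- if (length(controls)) {
    colMeans(as.matrix(m[controls, , drop = FALSE]))
  } else 0
  res <- tibble::tibble(cell_id = dataset$cell_ids,
                        score = as.numeric(set_mean - ctrl_mean))
  structure(res, class = c("module_score_result", class(res)),
            params = list(genes_used = present, n_bins = n_bins,
                          n_ctrl = n_ctrl, seed = seed))
}

#' Compare signature scores between two groups of cells
#'
#' Two-sided Mann-Whitney test of per-cell scores.
#'
#' @param module_scores a [module_score()] result.
#' @param groups named list of two cell-id vectors, or a factor/character
#'   vector aligned with the score rows.
#' @return One-row test-result tibble.
#' @export
score_group_test <- function(module_scores, groups) {
  sc <- module_scores
  if (is.list(groups)) {
    if (length(groups) != 2) {
      rlang::abort("exactly two groups required.",
                   class = "anchortraj_validation_error")
    }
    x <- sc$score[match(groups[[1]], sc$cell_id)]
    y <- sc$score[match(groups[[2]], sc$cell_id)]
  } else {
    lev <- unique(groups)
    if (length(lev) != 2) {
      rlang::abort("exactly two groups required.",
                   class = "anchortraj_validation_error")
    }
    x <- sc$score[groups == lev[1]]
    y <- sc$score[groups == lev[2]]
  }
  mann_whitney(x, y)
}
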