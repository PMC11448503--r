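#' Anchor-gene co-expression module on selected cells
#'
#' Over a supplied cell subset (typically the cells assigned to the
#' aberrant-branch lineage), computes the Spearman correlation of every
#' candidate gene with the anchor on normalized expression, BH-adjusts
#' across candidates, and retains genes with `q < fdr_threshold`, sorted by
#' `|rho|` descending. Candidate genes are those (excluding the anchor)
#' detected in at least `min_detect_frac` of the selected cells.
#'
#' @param dataset [expression_dataset()] with a normalized layer.
#' @param cells cell ids to use (>= 30).
#' @param anchor anchor gene id; must be detected in >= 3 selected cells.
#' @param fdr_threshold module FDR cutoff (default 0.2).
#' @param min_detect_frac candidate detection fraction (default 0.05).
#' @return A `coexpression_module`: list with `table` (retained genes:
#'   tibble gene/rho/p/q), `candidates` (all tested genes with statistics),
#'   `anchor`, `dataset_id`, `cells_used`, and parameters.
#' @export
anchor_module <- function(dataset, cells, anchor, fdr_threshold = 0.2,
                          min_detect_frac = 0.05) {
  stopifnot(inherits(dataset, "expression_dataset"))
  bad <- setdiff(cells, dataset$cell_ids)
  if (length(bad)) rlang::abort(sprintf("unknown cell id: %s", bad[1]),
                                class = "anchortraj_validation_error")
  if (length(cells) < 30) {
    rlang::abort("need >= 30 cells for stable correlations.",
                 class = "anchortraj_validation_error")
  }
  if (!anchor %in% dataset$gene_ids) {
    rlang::abort(sprintf("anchor gene %s absent.", anchor),
                 class = "anchortraj_validation_error")
  }
  counts <- dataset$counts[, cells, drop = FALSE]
  if (sum(counts[anchor, ] > 0) < 3) {
    rlang::abort(sprintf("anchor %s detected in fewer than 3 selected cells.",
                         anchor),
                 class = "anchortraj_validation_error")
  }
  detect <- Matrix::rowMeans(counts > 0)
  cand <- setdiff(names(which(detect >= min_detect_frac)), anchor)
  m <- normalized_matrix(dataset, genes = c(anchor, cand), cells = cells)
  if (!length(cand)) {
    rlang::abort("no candidate genes pass the detection filter.",
                 class = "anchortraj_validation_error")
  }
  av <- m[anchor, ]
  # apply() over rows yields a cells-by-genes rank matrix, as cor() expects
  rho <- unname(drop(stats::cor(rank(av), apply(m[cand, , drop = FALSE], 1, rank))))
  p <- spearman_p(rho, length(cells))
  candidates <- tibble::tibble(gene = cand, rho = rho, p = p, q = bh_fdr(p))
  table <- candidates[candidates$q < fdr_threshold, ]
  table <- table[order(-abs(table$rho), table$gene), ]
  structure(list(anchor = anchor,
                 dataset_id = unique(dataset$cell_meta$dataset_id)[1],
                 table = table, candidates = candidates,
                 cells_used = cells,
                 fdr_threshold = fdr_threshold,
                 min_detect_frac = min_detect_frac,
                 layer = "normalized"),
            class = "coexpression_module")
}

#' @export
print.coexpression_module <- function(x, ...) {
  cat(sprintf("<coexpression_module> anchor %s (%s): %d/%d genes at FDR < %g\n",
              x$anchor, x$dataset_id, nrow(x$table), nrow(x$candidates),
              x$fdr_threshold))
  invisible(x)
}

#' Intersect two anchor modules across datasets
#'
#' @param module_a,module_b [anchor_module()] results sharing one anchor.
#' @return A `module_intersection`: list with the sorted intersection
#'   `genes` and the per-dataset module sizes.
#' @export
intersect_modules <- function(module_a, module_b) {
  stopifnot(inherits(module_a, "coexpression_module"),
            inherits(module_b, "coexpression_module"))
  if (!identical(module_a$anchor, module_b$anchor)) {
    rlang::abort(sprintf("modules have different anchors (%s vs %s).",
                         module_a$anchor, module_b$anchor),
                 class = "anchortraj_validation_error")
  }
  structure(list(anchor = module_a$anchor,
                 genes = sort(intersect(module_a$table$gene,
                                        module_b$table$gene)),
                 size_a = nrow(module_a$table), size_b = nrow(module_b$table),
                 dataset_a = module_a$dataset_id,
                 dataset_b = module_b$dataset_id),
            class = "module_intersection")
}

#' @export
print.module_intersection <- function(x, ...) {
  cat(sprintf("<module_intersection> anchor %s: %d (%s) / %d (%s) / %d shared\n",
              x$anchor, x$size_a, x$dataset_a, x$size_b, x$dataset_b,
              length(x$genes)))
  invisible(x)
}

#' All-pairs Spearman co-expression network over a gene panel
#'
#' Computes the Spearman correlation between every pair of the supplied
#' genes (plus the anchor if given) over the selected cells; edges with
#' `|rho| >= edge_min_abs_rho` are kept (default 0: complete graph).
#'
#' @param dataset [expression_dataset()] with a normalized layer.
#' @param cells cell ids (>= 30).
#' @param genes node genes.
#' @param anchor optional anchor gene appended to the node list.
#' @param edge_min_abs_rho absolute-correlation edge filter.
#' @return A `network_edges`: list with `nodes` (tibble gene/is_anchor) and
#'   `edges` (tibble gene_i/gene_j/rho, i before j in node order).
#' @export
build_network <- function(dataset, cells, genes, anchor = NULL,
                          edge_min_abs_rho = 0) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(cells) < 30) {
    rlang::abort("need >= 30 cells.", class = "anchortraj_validation_error")
  }
  nodes <- unique(c(genes, anchor))
  missing <- setdiff(nodes, dataset$gene_ids)
  if (length(missing)) {
    rlang::abort(sprintf("gene absent from dataset: %s", missing[1]),
                 class = "anchortraj_validation_error")
  }
  m <- normalized_matrix(dataset, genes = nodes, cells = cells)
  rho <- stats::cor(t(m), method = "spearman")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- tibble::tibble(gene_i = nodes[idx[, 1]], gene_j = nodes[idx[, 2]],
                          rho = rho[idx])
  edges <- edges[abs(edges$rho) >= edge_min_abs_rho, ]
  structure(list(nodes = tibble::tibble(gene = nodes,
                                        is_anchor = nodes %in% anchor),
                 edges = edges, cells_used = cells,
                 edge_min_abs_rho = edge_min_abs_rho),
            class = "network_edges")
}

#' Write a co-expression network as node/edge tables
#' @param network a [build_network()] result.
#' @param out_dir directory for `nodes.tsv` and `edges.tsv`.
#' @return Paths, invisibly.
#' @export
write_network <- function(network, out_dir) {
  stopifnot(inherits(network, "network_edges"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(nodes = file.path(out_dir, "nodes.tsv"),
             edges = file.path(out_dir, "edges.tsv"))
  write_table(network$nodes, paths[["nodes"]], "tsv")
  write_table(network$edges, paths[["edges"]], "tsv")
  invisible(paths)
}

#' Compare anchor-module correlation distributions between conditions
#'
#' For each condition, computes the vector of Spearman correlations between
#' the anchor and every module gene over that condition's cells, then
#' contrasts the two correlation distributions with the two-sample
#' Kolmogorov-Smirnov test. Module genes undetected in a condition's cells
#' are skipped for that condition (with a note); more than 50% skipped is
#' an error.
#'
#' @param dataset [expression_dataset()] with a normalized layer.
#' @param cells_by_condition named list of two cell-id vectors (>= 30
#'   each).
#' @param anchor anchor gene id.
#' @param module character vector of module genes (>= 2).
#' @return A `condition_correlation_comparison`: list with `rho` (named
#'   list of per-condition correlation vectors), `ks` (test-result tibble)
#'   and `skipped`.
#' @export
condition_correlation_comparison <- function(dataset, cells_by_condition,
                                             anchor, module) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(cells_by_condition) != 2 || is.null(names(cells_by_condition))) {
    rlang::abort("cells_by_condition must be a named list of two cell sets.",
                 class = "anchortraj_validation_error")
  }
  if (length(module) < 2) {
    rlang::abort("module of fewer than 2 genes gives a degenerate distribution.",
                 class = "anchortraj_validation_error")
  }
  small <- which(lengths(cells_by_condition) < 30)
  if (length(small)) {
    rlang::abort(sprintf("condition %s has fewer than 30 cells.",
                         names(cells_by_condition)[small[1]]),
                 class = "anchortraj_validation_error")
  }
  skipped <- list()
  rho <- lapply(names(cells_by_condition), function(cond) {
    cells <- cells_by_condition[[cond]]
    counts <- dataset$counts[module, cells, drop = FALSE]
    ok <- Matrix::rowSums(counts > 0) > 0
    if (any(!ok)) {
      skipped[[cond]] <<- module[!ok]
      rlang::inform(sprintf("%d module gene(s) undetected in %s cells; skipped.",
                            sum(!ok), cond))
    }
    if (mean(!ok) > 0.5) {
      rlang::abort(sprintf("more than half the module undetected in %s cells.",
                           cond),
                   class = "anchortraj_validation_error")
    }
    m <- normalized_matrix(dataset, genes = c(anchor, module[ok]), cells = cells)
    drop(stats::cor(rank(m[anchor, ]),
                    apply(m[module[ok], , drop = FALSE], 1, rank)))
  })
  names(rho) <- names(cells_by_condition)
  structure(list(rho = rho,
                 ks = ks_two_sample(rho[[1]], rho[[2]]),
                 skipped = skipped, anchor = anchor),
            class = "condition_correlation_comparison")
}

#' Hypergeometric pathway over-representation test
#'
#' For each gene set: `k = |query ∩ term ∩ universe|`,
#' `K = |term ∩ universe|`, `n = |query|`, `N = |universe|`;
#' `p = P(X >= k)` under the hypergeometric null, BH-adjusted across terms;
#' rows with `q < fdr_threshold` are retained, sorted by p. Terms with no
#' universe overlap are skipped.
#'
#' @param query_genes genes of interest (must lie inside `universe`).
#' @param collection a [gene_set_collection()] or named list of gene
#'   vectors.
#' @param universe background gene ids (typically all genes tested when the
#'   query was formed).
#' @param fdr_threshold retention cutoff (default 0.1).
#' @return Tibble with columns `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `genes` (list-column of overlaps).
#' @export
pathway_enrichment <- function(query_genes, collection, universe,
                               fdr_threshold = 0.1) {
  sets <- as_gene_set_list(collection)
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (!length(query_genes)) {
    rlang::abort("empty query gene list.", class = "anchortraj_validation_error")
  }
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    rlang::abort(sprintf("query gene %s is not in the universe.", outside[1]),
                 class = "anchortraj_validation_error")
  }
  rows <- purrr::map_dfr(names(sets), function(term) {
    in_univ <- intersect(sets[[term]], universe)
    if (!length(in_univ)) return(NULL)
    hit <- intersect(query_genes, in_univ)
    p <- hypergeom_upper(length(hit), length(in_univ), length(query_genes),
                         length(universe))$p_value
    tibble::tibble(term = term, k = length(hit), K = length(in_univ),
                   n = length(query_genes), N = length(universe), p = p,
                   genes = list(sort(hit)))
  })
  if (is.null(rows) || !nrow(rows)) return(empty_enrichment_table())
  rows$q <- bh_fdr(rows$p)
  rows <- rows[rows$q < fdr_threshold, ]
  rows <- rows[order(rows$p, rows$term),
               c("term", "k", "K", "n", "N", "p", "q", "genes")]
  rows
}

empty_enrichment_table <- function() {
  tibble::tibble(term = character(), k = integer(), K = integer(),
                 n = integer(), N = integer(), p = numeric(), q = numeric(),
                 genes = list())
}
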