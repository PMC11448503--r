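#' Pipeline configuration
#'
#' A single configuration object driving [run_pipeline()]. All thresholds
#' default to the pipeline's canonical values: module FDR 0.2, pathway FDR
#' 0.1, marker fold-change quantile 0.85, marker detection proportion 0.40,
#' GSEA with 1e5 permutations.
#'
#' @param origin_cluster,aberrant_cluster,anchor_gene analysis anchors:
#'   trajectory origin, the aberrant terminal cluster, and the anchor gene.
#' @param ref,query input bundle directories (as written by
#'   [write_mtx_bundle()]); may be `NULL` when datasets are passed to
#'   [run_pipeline()] directly.
#' @param qc a [qc_thresholds()] list.
#' @param fdr_module,fdr_pathway,fc_quantile,min_prop stage thresholds.
#' @param gsea_n_perm,gsea_weight preranked GSEA parameters.
#' @param gene_sets optional GMT path or [gene_set_collection()] for
#'   pathway enrichment / GSEA stages.
#' @param disease_condition condition treated as disease.
#' @param seed root seed; per-stage substreams are derived from it.
#' @param output_dir artifact directory (`NULL` for no file output).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(origin_cluster, aberrant_cluster, anchor_gene,
                            ref = NULL, query = NULL,
                            qc = qc_thresholds(),
                            fdr_module = 0.2, fdr_pathway = 0.1,
                            fc_quantile = 0.85, min_prop = 0.40,
                            gsea_n_perm = 1e5, gsea_weight = 1,
                            gene_sets = NULL,
                            disease_condition = "PF",
                            seed = 1L, output_dir = NULL) {
  structure(list(origin_cluster = origin_cluster,
                 aberrant_cluster = aberrant_cluster,
                 anchor_gene = anchor_gene, ref = ref, query = query,
                 qc = qc, fdr_module = fdr_module, fdr_pathway = fdr_pathway,
                 fc_quantile = fc_quantile, min_prop = min_prop,
                 gsea_n_perm = gsea_n_perm, gsea_weight = gsea_weight,
                 gene_sets = gene_sets,
                 disease_condition = disease_condition,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates: QC -> normalisation -> (label transfer with Jaccard QC
#' when a query dataset is given) -> marker selection + Jaccard matrix ->
#' lineage inference + pseudotime -> anchor trajectory report -> anchor
#' co-expression module per dataset -> cross-dataset intersection ->
#' network -> condition KS comparison -> pathway enrichment ->
#' expressing-cell enrichment, plus (when gene sets are supplied)
#' pseudobulk + preranked GSEA + leading-edge set + module scoring. Every
#' artifact is written under `config$output_dir` (when set) together with
#' a `manifest.json` recording the configuration hash, seed and per-stage
#' row counts.
#'
#' @param config a [pipeline_config()].
#' @param ref,query optional [expression_dataset()]s overriding the bundle
#'   paths in the config.
#' @return A `pipeline_result` list of per-stage results plus `manifest`.
#' @export
run_pipeline <- function(config, ref = NULL, query = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(ref)) {
    if (is.null(config$ref)) {
      rlang::abort("no reference dataset supplied.",
                   class = "anchortraj_config_error")
    }
    ref <- read_bundle_dir(config$ref)
  }
  if (is.null(query) && !is.null(config$query)) {
    query <- read_bundle_dir(config$query)
  }
  if (!config$anchor_gene %in% ref$gene_ids) {
    rlang::abort(sprintf("anchor gene %s absent from the reference dataset.",
                         config$anchor_gene),
                 class = "anchortraj_config_error")
  }
  if (!config$origin_cluster %in% ref$cell_meta$cluster_label ||
      !config$aberrant_cluster %in% ref$cell_meta$cluster_label) {
    rlang::abort("origin/aberrant cluster absent from the reference labels.",
                 class = "anchortraj_config_error")
  }
  out <- list(config = config)
  stages <- character()
  record <- function(name, n) stages[[name]] <<- as.character(n)

  # --- QC + normalisation ------------------------------------------------
  qc_ref <- qc_filter(ref, config$qc)
  ref <- normalize_log(qc_ref$dataset)
  out$qc_ref <- qc_ref$report
  record("qc_ref", ncol(ref$counts))
  if (!is.null(query)) {
    qc_q <- qc_filter(query, config$qc)
    query <- normalize_log(qc_q$dataset)
    out$qc_query <- qc_q$report
    record("qc_query", ncol(query$counts))
  }

  # --- label transfer + marker Jaccard QC -------------------------------
  if (!is.null(query)) {
    out$transfer <- transfer_labels(ref, query)
    query$cell_meta$cluster_label <-
      out$transfer$predicted_label[match(query$cell_ids, out$transfer$cell_id)]
    record("transfer", nrow(out$transfer))
  }
  out$markers_ref <- rank_sum_markers(ref)
  out$marker_sets_ref <- select_markers(out$markers_ref, config$fc_quantile,
                                        config$min_prop)
  record("markers", nrow(out$markers_ref))
  if (!is.null(query)) {
    out$markers_query <- rank_sum_markers(query)
    out$marker_sets_query <- select_markers(out$markers_query,
                                            config$fc_quantile, config$min_prop)
    out$jaccard <- jaccard_matrix(out$marker_sets_ref, out$marker_sets_query)
  } else {
    out$jaccard <- jaccard_matrix(out$marker_sets_ref)
  }
  record("jaccard", length(out$jaccard))

  # --- trajectory -------------------------------------------------------
  if (is.null(ref$embedding)) {
    hvgs <- select_hvgs(ref, min(2000, length(ref$gene_ids)))
    ref$embedding <- pca_embed(ref, hvgs, n_components = 8)$embedding
  }
  model <- infer_lineages(ref$embedding, ref$cell_meta$cluster_label,
                          config$origin_cluster)
  model <- compute_pseudotime(model, ref$embedding,
                              ref$cell_meta$cluster_label)
  out$lineages <- model
  record("trajectory", length(model$lineages))
  out$anchor_report <- anchor_trajectory_report(ref, model, config$anchor_gene)
  record("anchor_report", nrow(out$anchor_report$summary))

  # --- co-expression along the aberrant lineage -------------------------
  aberrant_lineage <- which(vapply(model$lineages, function(l) {
    config$aberrant_cluster %in% l
  }, TRUE))[1]
  if (is.na(aberrant_lineage)) {
    rlang::abort(sprintf("no lineage reaches cluster %s.",
                         config$aberrant_cluster),
                 class = "anchortraj_pipeline_error")
  }
  traj_cells <- ref$cell_ids[!is.na(model$pseudotime[ref$cell_ids,
                                                     aberrant_lineage])]
  disease <- ref$cell_meta$condition == config$disease_condition
  module_cells <- intersect(traj_cells, ref$cell_ids[disease])
  if (length(module_cells) < 30) module_cells <- traj_cells
  out$module_ref <- anchor_module(ref, module_cells, config$anchor_gene,
                                  config$fdr_module)
  record("module_ref", nrow(out$module_ref$table))
  if (!is.null(query)) {
    if (is.null(query$embedding)) {
      query$embedding <- pca_embed(
        query, select_hvgs(query, min(2000, length(query$gene_ids))),
        n_components = 8)$embedding
    }
    q_model <- infer_lineages(query$embedding, query$cell_meta$cluster_label,
                              config$origin_cluster)
    q_model <- compute_pseudotime(q_model, query$embedding,
                                  query$cell_meta$cluster_label)
    q_ab <- which(vapply(q_model$lineages, function(l) {
      config$aberrant_cluster %in% l
    }, TRUE))[1]
    q_cells <- query$cell_ids[!is.na(q_model$pseudotime[query$cell_ids, q_ab])]
    q_disease <- query$cell_meta$condition == config$disease_condition
    q_module_cells <- intersect(q_cells, query$cell_ids[q_disease])
    if (length(q_module_cells) < 30) q_module_cells <- q_cells
    out$module_query <- anchor_module(query, q_module_cells,
                                      config$anchor_gene, config$fdr_module)
    out$intersection <- intersect_modules(out$module_ref, out$module_query)
    record("intersection", length(out$intersection$genes))
    network_genes <- out$intersection$genes
  } else {
    network_genes <- out$module_ref$table$gene
  }

  if (length(network_genes) >= 2) {
    out$network <- build_network(ref, module_cells, network_genes,
                                 anchor = config$anchor_gene)
    record("network", nrow(out$network$edges))
  }

  # --- condition contrast of module correlations ------------------------
  module_genes <- out$module_ref$table$gene
  cond_cells <- split(traj_cells,
                      ref$cell_meta$condition[match(traj_cells, ref$cell_ids)])
  if (length(module_genes) >= 2 && length(cond_cells) == 2 &&
      all(lengths(cond_cells) >= 30)) {
    out$condition_ks <- condition_correlation_comparison(
      ref, cond_cells, config$anchor_gene, module_genes)
    record("condition_ks", 1)
  }

  # --- enrichment -------------------------------------------------------
  if (!is.null(config$gene_sets) && length(module_genes)) {
    gs <- if (is.character(config$gene_sets)) read_gmt(config$gene_sets)
          else config$gene_sets
    out$pathways <- pathway_enrichment(module_genes, gs,
                                       universe = out$module_ref$candidates$gene,
                                       fdr_threshold = config$fdr_pathway)
    record("pathways", nrow(out$pathways))
  }
  out$expressing <- expressing_cell_enrichment(ref, config$anchor_gene,
                                               config$aberrant_cluster)
  out$expression_test <- expression_group_test(ref, config$anchor_gene,
                                               config$aberrant_cluster)
  record("expressing", nrow(out$expressing$stats))

  # --- signatures (needs gene sets and >= 2 samples per condition) ------
  if (!is.null(config$gene_sets)) {
    gs <- if (is.character(config$gene_sets)) read_gmt(config$gene_sets)
          else config$gene_sets
    aberrant_cells <- ref$cell_ids[ref$cell_meta$cluster_label ==
                                     config$aberrant_cluster]
    pb <- pseudobulk_aggregate(ref, aberrant_cells)
    conds <- ref$cell_meta$condition[match(aberrant_cells, ref$cell_ids)]
    samp_cond <- unique(tibble::tibble(
      sample = ref$cell_meta$sample_id[match(aberrant_cells, ref$cell_ids)],
      cond = conds))
    ga <- intersect(samp_cond$sample[samp_cond$cond == config$disease_condition],
                    rownames(pb))
    gb <- intersect(samp_cond$sample[samp_cond$cond != config$disease_condition],
                    rownames(pb))
    if (length(ga) >= 2 && length(gb) >= 2) {
      ranks <- rank_genes(pb, ga, gb)
      out$gsea <- gsea_preranked(ranks, gs, n_perm = config$gsea_n_perm,
                                 weight = config$gsea_weight,
                                 seed = config$seed)
      record("gsea", nrow(out$gsea))
      top <- out$gsea$set[which.min(out$gsea$p)]
      le <- leading_edge_gene_set(out$gsea, top)
      out$leading_edge <- le
      out$scores <- module_score(ref, le$genes[[1]], seed = config$seed)
      record("scores", nrow(out$scores))
    }
  }

  out$manifest <- build_manifest(config, stages)
  if (!is.null(config$output_dir)) write_pipeline_artifacts(out)
  structure(out, class = "pipeline_result")
}

read_bundle_dir <- function(dir) {
  meta <- file.path(dir, "cell_meta.tsv")
  read_mtx_bundle(file.path(dir, "matrix.mtx"), file.path(dir, "features.tsv"),
                  file.path(dir, "barcodes.tsv"),
                  meta_path = if (file.exists(meta)) meta else NULL)
}

build_manifest <- function(config, stages) {
  cfg <- unclass(config)
  cfg$qc <- unclass(cfg$qc)
  cfg$gene_sets <- if (is.character(cfg$gene_sets)) cfg$gene_sets else NULL
  list(config_hash = rlang::hash(cfg), seed = config$seed,
       package_version = as.character(utils::packageVersion("anchortraj")),
       stages = as.list(stages))
}

write_pipeline_artifacts <- function(out) {
  dir <- out$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(out$markers_ref, file.path(dir, "markers_ref.tsv"), "tsv")
  utils::write.table(out$jaccard, file.path(dir, "jaccard.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  if (!is.null(out$transfer)) {
    write_table(out$transfer, file.path(dir, "label_transfer.tsv"), "tsv")
  }
  jsonlite::write_json(
    list(origin = out$lineages$origin, lineages = out$lineages$lineages,
         centroids = as.data.frame(out$lineages$centroids)),
    file.path(dir, "lineages.json"), digits = 12, auto_unbox = TRUE)
  pt <- out$lineages$pseudotime
  pt_long <- tidyr::pivot_longer(
    tibble::as_tibble(pt, rownames = "cell_id"),
    -"cell_id", names_to = "lineage", values_to = "pseudotime")
  write_table(pt_long[!is.na(pt_long$pseudotime), ],
              file.path(dir, "pseudotime.tsv"), "tsv")
  write_table(out$anchor_report$summary, file.path(dir, "anchor_report.tsv"),
              "tsv")
  write_table(out$module_ref$table, file.path(dir, "module_ref.tsv"), "tsv")
  if (!is.null(out$module_query)) {
    write_table(out$module_query$table, file.path(dir, "module_query.tsv"),
                "tsv")
    writeLines(out$intersection$genes, file.path(dir, "module_intersection.txt"))
  }
  if (!is.null(out$network)) write_network(out$network, dir)
  if (!is.null(out$condition_ks)) {
    write_table(out$condition_ks$ks, file.path(dir, "condition_ks.tsv"), "tsv")
  }
  if (!is.null(out$pathways)) {
    pw <- out$pathways
    pw$genes <- vapply(pw$genes, paste, "", collapse = ",")
    write_table(pw, file.path(dir, "pathways.tsv"), "tsv")
  }
  write_table(out$expressing$stats, file.path(dir, "expressing_cells.tsv"),
              "tsv")
  if (!is.null(out$gsea)) {
    gs <- out$gsea
    gs$leading_edge <- vapply(gs$leading_edge, paste, "", collapse = ",")
    write_table(gs, file.path(dir, "gsea.tsv"), "tsv")
    write_gmt(out$leading_edge, file.path(dir, "leading_edge.gmt"))
    write_table(out$scores, file.path(dir, "module_scores.tsv"), "tsv")
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$manifest$stages)) {
    cat(sprintf("  %-14s %s\n", nm, x$manifest$stages[[nm]]))
  }
  invisible(x)
}
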