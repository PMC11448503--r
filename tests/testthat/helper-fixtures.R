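# Shared fixtures. Simulated datasets are cached per (seed, tag) so test
# files exercising the same study conditions do not regenerate them.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed, cfg_fun = sim_config, tag = "default") {
  key <- paste0(tag, "_", seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  sim <- generate_dataset(cfg_fun(seed = seed))
  sim$dataset <- normalize_log(sim$dataset)
  # cap the cache so wide seed sweeps do not accumulate memory
  if (seed <= 20 && length(ls(.sim_cache)) < 25) .sim_cache[[key]] <- sim
  sim
}

b_lineage_clusters <- c("Transitional_AT2", "Basaloid_intermediate", "KRT5_KRT17")

branch_b_disease_cells <- function(truth) {
  truth$cells$cell_id[truth$cells$branch == "B" & truth$cells$condition == "PF"]
}

lineage_disease_cells <- function(truth) {
  truth$cells$cell_id[truth$cells$cluster %in% b_lineage_clusters &
                        truth$cells$condition == "PF"]
}

module_truth_genes <- function(truth) {
  truth$genes$gene[truth$genes$role == "module"]
}

# Small fully deterministic dataset for container/IO tests.
toy_dataset <- function(n_genes = 4, n_cells = 3, seed = 42) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells,
                     dimnames = list(paste0("g", seq_len(n_genes)),
                                     paste0("c", seq_len(n_cells))))
  })
  meta <- tibble::tibble(cell_id = colnames(counts),
                         cluster_label = rep(c("A", "B"),
                                             length.out = n_cells),
                         condition = "Control", sample_id = "s1",
                         dataset_id = "toy")
  expression_dataset(counts, cell_meta = meta)
}

# Designed 8-cell QC fixture. Each of the four failing cells violates
# exactly one cell criterion; gene_low is seen in only 2 cells so the gene
# filter (>= 3 cells) removes exactly one gene. Survivors: c5..c8.
#   c1: 199 genes x3 (umi 597, ratio .828)      -> fails min_genes only
#   c2: 200 genes x1 (umi 200, ratio 1)         -> fails min_umi only
#   c3: 205 genes, umi 5000 (ratio .625)        -> fails log10GenesPerUMI only
#   c4: 290 genes x2 + 290 mito (mito .333)     -> fails mito fraction only
qc_fixture <- function() {
  genes <- c(paste0("g", 1:290), "mt-x", "gene_low")
  counts <- matrix(0L, length(genes), 8,
                   dimnames = list(genes, paste0("c", 1:8)))
  for (j in 5:8) {
    counts[1:290, j] <- 3L
    counts["mt-x", j] <- 1L
  }
  counts[1:199, 1] <- 3L
  counts[1:200, 2] <- 1L
  counts[1:204, 3] <- 1L; counts[205, 3] <- 4796L
  counts[1:290, 4] <- 2L; counts["mt-x", 4] <- 290L
  counts["gene_low", 5] <- 1L; counts["gene_low", 6] <- 1L
  expression_dataset(counts)
}
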