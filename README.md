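# anchortraj

Characterising an anchor gene along aberrant single-cell differentiation
trajectories.

In fibrotic lung disease, transitional AT2 cells can fail to complete
differentiation into AT1 cells and instead accumulate in an aberrant
basaloid-like state (KRT5-/KRT17+ in human disease, Krt8+ ADI in mouse
injury). `anchortraj` is an R package for asking, quantitatively, what a
gene of interest — the *anchor*, e.g. the cytokine IL11 — is doing along
that aberrant path:

* **QC and normalisation** — droplet-style filters (>= 200 genes,
  >= 500 UMI, log10(genes)/log10(UMI) > 0.8, < 30% mitochondrial reads,
  genes in >= 3 cells) and `ln(1 + 1e4 * count / total)` normalisation.
* **Cluster similarity and label transfer** — rank-sum marker tables, the
  85th-percentile log2FC + 40% detection marker rule, Jaccard similarity
  matrices between cluster marker sets, and a deterministic kNN-in-PCA
  label transfer from a reference to a query dataset.
* **Trajectories** — origin-rooted lineages from a minimum spanning tree
  over cluster centroids, per-cell pseudotime by orthogonal projection
  onto piecewise-linear centroid paths, and a cubic B-spline F-test of
  `expr ~ s(pseudotime)` per lineage, flagging lineages with BH q < 0.05.
* **Co-expression modules** — Spearman correlation of every expressed gene
  with the anchor over trajectory cells, BH FDR < 0.2 retention,
  cross-dataset intersection, network export (nodes/edges TSV), a
  two-sample KS contrast of correlation distributions between conditions,
  and a local hypergeometric pathway over-representation test (FDR < 0.1).
* **Enrichment statistics** — one-tailed hypergeometric expressing-cell
  enrichment and two-sided Mann-Whitney expression tests per cluster.
* **Signatures** — pseudobulk aggregation, a Welch-t ranking statistic,
  preranked permutation GSEA (gene-permutation null, sign-matched NES,
  1e5 permutations by default) with leading-edge GMT export, and
  binned-control module scoring.
* **A ground-truth simulator** — seeded negative-binomial datasets with a
  bifurcating latent trajectory, a disease-specific anchor-module
  coupling, cluster markers, batch-paired dataset pairs, and full truth
  export, used to validate every stage.

Results are tibbles throughout; fitted objects have `tidy()` / `glance()`
methods and `autoplot()` visualisations, so everything drops into a
dplyr/ggplot2 workflow.

## Worked example

Simulate the default study conditions (2000 genes x 2000 cells, a
bifurcating trajectory with an IL11-like anchor coupled to a 40-gene
module in disease cells only), then run the trajectory and module stages:

```r
library(anchortraj)

sim <- generate_dataset(sim_config(seed = 42))
d <- normalize_log(sim$dataset)

model <- infer_lineages(d$embedding, d$cell_meta$cluster_label,
                        origin = "Transitional_AT2")
model <- compute_pseudotime(model, d$embedding, d$cell_meta$cluster_label)
model
#> <lineage_model> origin: Transitional_AT2; 2 lineage(s)
#>    Transitional_AT2 -> AT1_intermediate -> AT1
#>    Transitional_AT2 -> Basaloid_intermediate -> KRT5_KRT17
#>   pseudotime: 2000 cells assigned

tidy(anchor_trajectory_report(d, model, "IL11"))
#>   lineage   terminus n_cells            p terminal_mean            q flagged
#> 1       1        AT1    1191 8.915222e-01     0.8600216 8.915222e-01   FALSE
#> 2       2 KRT5_KRT17    1388 1.159655e-06     1.3221355 2.319311e-06    TRUE
```

The anchor is associated with pseudotime only on the aberrant branch
(q = 2.3e-6 versus 0.89 on the AT1 branch), reproducing the
disease-trajectory-specific expression pattern the method is built to
detect. Restricting to disease cells assigned to that lineage, module
discovery at FDR < 0.2 retains the co-expressed partners of the anchor:

```r
cells <- subset(tidy(model), terminus == "KRT5_KRT17")$cell_id
disease <- intersect(cells, d$cell_ids[d$cell_meta$condition == "PF"])
anchor_module(d, disease, "IL11")
#> <coexpression_module> anchor IL11 (sim): 47/1927 genes at FDR < 0.2

expressing_cell_enrichment(sim$dataset, "IL11", "KRT5_KRT17")$test
#>   statistic      p_value               method n_x  n_y
#> 1       269 4.222487e-05 hypergeometric-upper 390 2000
```

Of 1927 testable genes, 47 pass FDR < 0.2 (the planted module has 40
members; at FDR 0.2 roughly a fifth of retained genes are expected to be
noise), and IL11-expressing cells are significantly enriched in the
aberrant terminal cluster (269 expressing cells of 390; one-tailed
hypergeometric p = 4.2e-5). `generate_paired_datasets()` produces a
batch-shifted dataset pair for label transfer and for intersecting modules
across cohorts, which is how false positives are pruned in practice.

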