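Package: anchortraj
Title: Anchor-Gene Co-Expression Modules Along Single-Cell Differentiation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterise a gene of interest (an "anchor", e.g. IL11)
    along aberrant differentiation trajectories in single-cell RNA-seq data.
    Provides 10x-style MatrixMarket and GMT input/output, quality-control
    filtering and normalisation, marker-based Jaccard cluster similarity,
    k-nearest-neighbour reference label transfer, origin-rooted minimum
    spanning tree lineage inference with per-cell pseudotime and spline-based
    pseudotime-expression association, trajectory-restricted Spearman
    co-expression module discovery with cross-dataset intersection and
    network export, expressing-cell enrichment statistics, preranked
    permutation GSEA with leading-edge gene-set construction, binned-control
    signature scoring, and a seeded negative-binomial simulator of branching
    lineages with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    splines,
    generics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
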