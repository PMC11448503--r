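test_that("a duplicated anchor row is always retained with rho 1", {
  sim <- cached_sim(1)
  d <- sim$dataset
  # graft an exact copy of the anchor onto a background gene
  d$counts["G0001", ] <- d$counts["IL11", ]
  d$normalized["G0001", ] <- d$normalized["IL11", ]
  cells <- branch_b_disease_cells(sim$truth)
  mod <- anchor_module(d, cells, "IL11")
  row <- mod$table[mod$table$gene == "G0001", ]
  expect_equal(row$rho, 1)
  expect_equal(row$q, min(mod$table$q))
  expect_identical(mod$table$gene[1], "G0001")   # sorted by |rho|
})

test_that("anchor_module validates cells, anchor and layer", {
  sim <- cached_sim(1)
  cells <- branch_b_disease_cells(sim$truth)
  expect_error(anchor_module(sim$dataset, cells[1:10], "IL11"), ">= 30",
               class = "anchortraj_validation_error")
  expect_error(anchor_module(sim$dataset, cells, "NOPE"), "absent",
               class = "anchortraj_validation_error")
  undetected <- sim$dataset
  undetected$counts["IL11", ] <- 0L
  undetected$normalized["IL11", ] <- 0
  expect_error(anchor_module(undetected, cells, "IL11"), "fewer than 3",
               class = "anchortraj_validation_error")
})

test_that("module discovery is a rank statistic: monotone transforms are no-ops", {
  sim <- cached_sim(1)
  cells <- branch_b_disease_cells(sim$truth)[1:200]
  base <- anchor_module(sim$dataset, cells, "IL11")
  rescaled <- sim$dataset
  rescaled$normalized@x <- rescaled$normalized@x^1.7  # strictly monotone on > 0
  again <- anchor_module(rescaled, cells, "IL11")
  expect_equal(base$table$rho, again$table$rho, tolerance = 1e-12)
  expect_identical(base$table$gene, again$table$gene)
})

test_that("module intersection checks anchors and sorts its output", {
  sim <- cached_sim(1)
  cells <- branch_b_disease_cells(sim$truth)
  a <- anchor_module(sim$dataset, cells, "IL11")
  b <- a
  b$table <- b$table[seq(1, nrow(b$table), by = 2), ]
  b$dataset_id <- "other"
  int <- intersect_modules(a, b)
  expect_identical(int$genes, sort(intersect(a$table$gene, b$table$gene)))
  expect_equal(int$size_a, nrow(a$table))
  b$anchor <- "OTHER"
  expect_error(intersect_modules(a, b), "different anchors",
               class = "anchortraj_validation_error")
})

test_that("network construction matches pairwise Spearman exactly", {
  sim <- cached_sim(1)
  cells <- branch_b_disease_cells(sim$truth)
  genes <- c("MOD001", "MOD002", "MOD003")
  net <- build_network(sim$dataset, cells, genes)
  expect_equal(nrow(net$edges), 3)   # C(3,2)
  for (i in seq_len(nrow(net$edges))) {
    x <- as.numeric(sim$dataset$normalized[net$edges$gene_i[i], cells])
    y <- as.numeric(sim$dataset$normalized[net$edges$gene_j[i], cells])
    expect_equal(net$edges$rho[i], spearman(x, y)$statistic, tolerance = 1e-12)
  }
  # raising the threshold only removes edges
  all_genes <- c(genes, "MOD004", "MOD005")
  loose <- build_network(sim$dataset, cells, all_genes, edge_min_abs_rho = 0)
  tight <- build_network(sim$dataset, cells, all_genes, edge_min_abs_rho = 0.3)
  key <- function(e) paste(e$gene_i, e$gene_j)
  expect_true(all(key(tight$edges) %in% key(loose$edges)))
  expect_error(build_network(sim$dataset, cells, c("MOD001", "NOPE")), "NOPE",
               class = "anchortraj_validation_error")
})

test_that("network export writes loadable node and edge tables", {
  sim <- cached_sim(1)
  cells <- branch_b_disease_cells(sim$truth)
  net <- build_network(sim$dataset, cells, c("MOD001", "MOD002"),
                       anchor = "IL11")
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  nodes <- read_table_file(paths[["nodes"]], "tsv")
  edges <- read_table_file(paths[["edges"]], "tsv")
  expect_setequal(nodes$gene, c("MOD001", "MOD002", "IL11"))
  expect_equal(nrow(edges), 3)
})

test_that("condition comparison validates inputs and reports per-gene rho", {
  sim <- cached_sim(1)
  tm <- module_truth_genes(sim$truth)
  tr <- sim$truth$cells
  sel <- tr$cell_id[tr$cluster %in% b_lineage_clusters]
  by_cond <- split(sel, tr$condition[match(sel, tr$cell_id)])
  cmp <- condition_correlation_comparison(sim$dataset, by_cond, "IL11", tm)
  expect_length(cmp$rho, 2)
  expect_true(all(lengths(cmp$rho) <= length(tm)))
  expect_lt(cmp$ks$p_value, 0.01)
  expect_gt(mean(cmp$rho$PF), mean(cmp$rho$Control))

  expect_error(condition_correlation_comparison(sim$dataset, by_cond, "IL11",
                                                tm[1]),
               "degenerate", class = "anchortraj_validation_error")
  expect_error(condition_correlation_comparison(
    sim$dataset, list(a = by_cond[[1]][1:5], b = by_cond[[2]]), "IL11", tm),
    "fewer than 30", class = "anchortraj_validation_error")
})

test_that("hypergeometric pathway enrichment matches the enumeration oracle", {
  # N=100, K=10, n=10, k=5 worked example
  universe <- paste0("u", 1:100)
  term <- universe[1:10]
  query <- c(universe[1:5], universe[50:54])
  res <- pathway_enrichment(query, list(T1 = term), universe, fdr_threshold = 1)
  expect_equal(res$p, oracle_hyper_upper(5, 10, 10, 100), tolerance = 1e-12)
  expect_equal(res$k, 5)

  # query equal to a term at reduced scale ranks first with the minimal p
  small_univ <- paste0("g", 1:60)
  sets <- list(hit = small_univ[1:8], other = small_univ[30:45])
  res2 <- pathway_enrichment(small_univ[1:8], sets, small_univ,
                             fdr_threshold = 1)
  expect_identical(res2$term[1], "hit")
  expect_equal(res2$p[1], oracle_hyper_upper(8, 8, 8, 60), tolerance = 1e-12)

  # no overlap anywhere -> empty retained table
  res3 <- pathway_enrichment(small_univ[50:55], list(t = small_univ[1:5]),
                             small_univ, fdr_threshold = 0.1)
  expect_equal(nrow(res3), 0)

  expect_error(pathway_enrichment(character(), sets, small_univ),
               "empty query", class = "anchortraj_validation_error")
  expect_error(pathway_enrichment("not_in_universe", sets, small_univ),
               "universe", class = "anchortraj_validation_error")
})
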