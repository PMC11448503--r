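test_that("pseudobulk aggregation is plain addition with conservation", {
  counts <- matrix(c(1L, 2L, 3L, 0L), 2, 2,
                   dimnames = list(c("gA", "gB"), c("c1", "c2")))
  meta <- tibble::tibble(cell_id = c("c1", "c2"), cluster_label = "x",
                         condition = "y", sample_id = "s1", dataset_id = "d")
  d <- expression_dataset(counts, cell_meta = meta)
  pb <- pseudobulk_aggregate(d, c("c1", "c2"))
  expect_equal(pb["s1", ], c(gA = 4, gB = 2))

  pb1 <- pseudobulk_aggregate(d, "c1")
  expect_equal(unname(pb1["s1", ]), as.numeric(counts[, "c1"]))

  sim <- cached_sim(1)
  cells <- sim$dataset$cell_ids[sim$dataset$cell_meta$cluster_label == "KRT5_KRT17"]
  pbs <- pseudobulk_aggregate(sim$dataset, cells)
  expect_equal(unname(colSums(pbs)),
               unname(Matrix::rowSums(sim$dataset$counts[, cells])))
  expect_error(pseudobulk_aggregate(sim$dataset, character()),
               class = "anchortraj_validation_error")
})

test_that("the ranking statistic separates groups and zeroes equal genes", {
  # equal library sizes so CPM differences come from composition alone;
  # g2 has identical values across groups -> statistic exactly 0
  pb <- rbind(s1 = c(g1 = 100, g2 = 50, g3 = 50),
              s2 = c(110, 52, 38),
              s3 = c(10, 50, 140),
              s4 = c(12, 52, 136))
  r <- rank_genes(pb, c("s1", "s2"), c("s3", "s4"))
  expect_identical(r$gene[1], "g1")        # strong positive separation first
  expect_gt(r$stat[r$gene == "g1"], 5)
  expect_equal(r$stat[r$gene == "g2"], 0)
  expect_error(rank_genes(pb, "s1", c("s3", "s4")),
               class = "anchortraj_validation_error")

  sim <- cached_sim(1)
  cells <- sim$dataset$cell_ids[sim$dataset$cell_meta$cluster_label %in%
                                  b_lineage_clusters]
  pb2 <- pseudobulk_aggregate(sim$dataset, cells)
  conds <- sub("_[0-9]+$", "", rownames(pb2))
  r2 <- rank_genes(pb2, rownames(pb2)[conds == "PF"],
                   rownames(pb2)[conds == "Control"])
  # module genes are disease-coupled but mean-centred; the anchor itself is
  # condition-balanced, so ranks should at least exist for all planted genes
  expect_true(all(module_truth_genes(sim$truth) %in% r2$gene))
})

test_that("the worked GSEA toy gives ES 2/3 with the right leading edge", {
  stats <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1)
  res <- gsea_preranked(stats, list(S = c("g1", "g3")), n_perm = 2000,
                        seed = 1, min_size = 1)
  expect_equal(res$ES, 2 / 3, tolerance = 1e-12)
  expect_identical(res$leading_edge[[1]], c("g1", "g3"))
  expect_gt(res$NES, 0)
  expect_gte(res$p, 1 / 2001)

  # bottom-ranked singleton: pin against the brute-force oracle
  res2 <- gsea_preranked(stats, list(S = "g5"), n_perm = 500, seed = 1,
                         min_size = 1)
  sorted <- sort(stats, decreasing = TRUE)
  expect_equal(res2$ES, oracle_gsea_es(sorted, "g5"), tolerance = 1e-12)
})

test_that("ES equals the brute-force running sum on random rankings", {
  for (i in 1:200) {
    withr::with_seed(i, {
      n <- sample(10:60, 1)
      stats <- stats::setNames(rnorm(n), paste0("g", sample(1e4, n)))
      k <- sample(2:min(8, n - 2), 1)
      set_genes <- sample(names(stats), k)
    })
    res <- gsea_preranked(stats, list(S = set_genes), n_perm = 2, seed = 1,
                          min_size = 1)
    sorted <- stats[order(-stats, names(stats))]
    expect_equal(res$ES, oracle_gsea_es(sorted, set_genes), tolerance = 1e-12)
    expect_true(abs(res$ES) <= 1 + 1e-12)
  }
})

test_that("permutation p-values are seed-reproducible and ES-independent of n_perm", {
  stats <- stats::setNames(withr::with_seed(5, rnorm(40)), paste0("g", 1:40))
  sets <- list(a = paste0("g", 1:6), b = paste0("g", 20:30))
  r1 <- gsea_preranked(stats, sets, n_perm = 3000, seed = 11)
  r2 <- gsea_preranked(stats, sets, n_perm = 3000, seed = 11)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$NES, r2$NES)
  r3 <- gsea_preranked(stats, sets, n_perm = 6000, seed = 12)
  expect_equal(r1$ES, r3$ES)
  expect_gte(min(r1$p), 1 / 3001)
})

test_that("gsea results agree with fgsea on a moderate example", {
  skip_if_not_installed("fgsea")
  withr::with_seed(3, {
    stats <- stats::setNames(rnorm(200), paste0("g", 1:200))
    sets <- list(s1 = paste0("g", sample(200, 15)),
                 s2 = paste0("g", sample(200, 25)))
  })
  mine <- gsea_preranked(stats, sets, n_perm = 20000, seed = 4)
  ref <- suppressWarnings(fgsea::fgseaSimple(sets, stats, nperm = 20000))
  ref <- ref[match(mine$set, ref$pathway), ]
  expect_equal(mine$ES, ref$ES, tolerance = 1e-10)
  expect_equal(mine$NES, ref$NES, tolerance = 0.1)
  expect_equal(mine$p, ref$pval, tolerance = 0.05)
  for (i in 1:2) {
    expect_setequal(mine$leading_edge[[i]], ref$leadingEdge[[i]])
  }
})

test_that("leading-edge sets export through GMT unchanged", {
  stats <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1)
  res <- gsea_preranked(stats, list(S = c("g1", "g3")), n_perm = 200,
                        seed = 1, min_size = 1)
  le <- leading_edge_gene_set(res, "S")
  expect_identical(le$set, "S_leading_edge")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(le, path)
  expect_identical(read_gmt(path)$genes[[1]], c("g1", "g3"))
  expect_error(leading_edge_gene_set(res, "missing"),
               class = "anchortraj_validation_error")
  expect_error(gsea_preranked(stats, list(S = "gX"), seed = 1),
               "size filter", class = "anchortraj_validation_error")
})

test_that("module scores are seeded, centred under null sets, and shift-invariant", {
  sim <- cached_sim(1)
  d <- sim$dataset
  set_genes <- module_truth_genes(sim$truth)
  s1 <- module_score(d, set_genes, seed = 3)
  s2 <- module_score(d, set_genes, seed = 3)
  expect_identical(s1$score, s2$score)

  null_sets <- withr::with_seed(6, replicate(5, sample(d$gene_ids, 30),
                                             simplify = FALSE))
  null_means <- sapply(seq_along(null_sets), function(i) {
    mean(module_score(d, null_sets[[i]], seed = i)$score)
  })
  expect_lt(abs(mean(null_means)), 0.05)

  # with whole-bin controls, adding a constant to the layer cancels exactly
  shifted <- d
  shifted$normalized <- d$normalized + 1
  a <- module_score(d, set_genes, n_ctrl = NULL, seed = 1)
  b <- module_score(shifted, set_genes, n_ctrl = NULL, seed = 1)
  expect_equal(a$score, b$score, tolerance = 1e-10)

  expect_error(module_score(d, c("nope1", "nope2"), seed = 1),
               class = "anchortraj_validation_error")
})

test_that("planted module scores separate disease from control cells", {
  # the disease program elevates module counts (x2^0.3) but the module's
  # latent-factor noise skews log-normalized means downward in disease, so
  # the separation, not its sign, is the robust planted signal
  for (seed in 1:3) {
    sim <- cached_sim(seed)
    tr <- sim$truth$cells
    tm <- module_truth_genes(sim$truth)
    ab <- tr$cell_id[tr$cluster == "KRT5_KRT17" & tr$condition == "PF"]
    org <- tr$cell_id[tr$cluster == "Transitional_AT2" & tr$condition == "Control"]
    raw_diff <- mean(Matrix::colMeans(sim$dataset$counts[tm, ab])) -
      mean(Matrix::colMeans(sim$dataset$counts[tm, org]))
    expect_gt(raw_diff, 0)   # raw-count elevation of the disease program
    sc <- module_score(sim$dataset, tm, seed = seed)
    grp <- score_group_test(sc, list(ab, org))
    expect_lt(grp$p_value, 0.01)
  }
  sim <- cached_sim(1)
  sc <- module_score(sim$dataset, module_truth_genes(sim$truth), seed = 1)
  tr <- sim$truth$cells
  groups <- list(tr$cell_id[tr$condition == "PF" & tr$branch == "B"],
                 tr$cell_id[tr$condition == "Control" & tr$branch == "B"])
  t1 <- score_group_test(sc, groups)
  t2 <- score_group_test(sc, rev(groups))
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
})
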