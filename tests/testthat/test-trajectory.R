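four_centroid_embedding <- function(per = 30, noise = 0.01, seed = 1) {
  centers <- rbind(A = c(0, 0), B = c(1, 0), C = c(2, 1), D = c(2, -1))
  withr::with_seed(seed, {
    emb <- centers[rep(1:4, each = per), ] +
      matrix(rnorm(4 * per * 2, sd = noise), ncol = 2)
  })
  rownames(emb) <- paste0("cell", seq_len(nrow(emb)))
  list(embedding = emb, labels = rep(rownames(centers), each = per))
}

test_that("MST lineages reproduce the hand-computed tree", {
  fx <- four_centroid_embedding()
  model <- infer_lineages(fx$embedding, fx$labels, origin = "A")
  expect_length(model$lineages, 2)
  expect_identical(model$lineages[[1]], c("A", "B", "C"))
  expect_identical(model$lineages[[2]], c("A", "B", "D"))
  edges <- apply(model$mst_edges, 1, function(e) paste(sort(e), collapse = ""))
  expect_setequal(edges, c("AB", "BC", "BD"))
})

test_that("collinear centroids give a single path lineage", {
  emb <- rbind(matrix(c(0, 0), 10, 2, byrow = TRUE),
               matrix(c(1, 0), 10, 2, byrow = TRUE),
               matrix(c(2, 0), 10, 2, byrow = TRUE)) +
    withr::with_seed(2, matrix(rnorm(60, sd = 0.01), 30, 2))
  labels <- rep(c("A", "B", "C"), each = 10)
  model <- infer_lineages(emb, labels, "A")
  expect_length(model$lineages, 1)
  expect_identical(model$lineages[[1]], c("A", "B", "C"))
  # origin at the end of the chain still yields the path from the origin
  model2 <- infer_lineages(emb, labels, "C")
  expect_identical(model2$lineages[[1]], c("C", "B", "A"))
})

test_that("lineage inference is invariant to rigid motions", {
  fx <- four_centroid_embedding()
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  emb2 <- fx$embedding %*% rot + 5
  m1 <- infer_lineages(fx$embedding, fx$labels, "A")
  m2 <- infer_lineages(emb2, fx$labels, "A")
  expect_identical(m1$lineages, m2$lineages)
})

test_that("origin/cluster validation errors fire", {
  fx <- four_centroid_embedding()
  expect_error(infer_lineages(fx$embedding, fx$labels, "Z"), "absent",
               class = "anchortraj_validation_error")
  expect_error(infer_lineages(fx$embedding, rep("A", nrow(fx$embedding)), "A"),
               "2 clusters", class = "anchortraj_validation_error")
})

test_that("pseudotime is the arc length to the orthogonal projection", {
  fx <- four_centroid_embedding(noise = 1e-9)
  model <- infer_lineages(fx$embedding, fx$labels, "A")
  # plant probes exactly at centroids B and A
  emb <- rbind(fx$embedding, atB = c(1, 0), atA = c(0, 0))
  labels <- c(fx$labels, "B", "A")
  model <- compute_pseudotime(model, emb, labels)
  expect_equal(unname(model$pseudotime["atB", ]), c(1, 1), tolerance = 1e-6)
  expect_equal(unname(model$pseudotime["atA", ]), c(0, 0), tolerance = 1e-6)
  # cells of cluster D are assigned only to the D lineage
  d_cell <- rownames(emb)[labels == "D"][1]
  expect_true(is.na(model$pseudotime[d_cell, "C"]))
  expect_false(is.na(model$pseudotime[d_cell, "D"]))
})

test_that("pseudotime increases along each lineage's cluster order", {
  sim <- cached_sim(1)
  model <- infer_lineages(sim$dataset$embedding,
                          sim$dataset$cell_meta$cluster_label,
                          "Transitional_AT2")
  model <- compute_pseudotime(model, sim$dataset$embedding,
                              sim$dataset$cell_meta$cluster_label)
  labels <- sim$dataset$cell_meta$cluster_label
  for (li in seq_along(model$lineages)) {
    path <- model$lineages[[li]]
    means <- sapply(path, function(cl) {
      mean(model$pseudotime[labels == cl, li], na.rm = TRUE)
    })
    expect_true(all(diff(means) > 0))
  }
})

test_that("the spline association test behaves at the extremes", {
  pt <- seq(0, 1, length.out = 60)
  flat <- fit_pseudotime_gam(pt, rep(2, 60))
  expect_equal(flat$p_association, 1)
  expect_equal(flat$f_statistic, 0)

  perfect <- fit_pseudotime_gam(pt, pt)
  expect_lt(perfect$p_association, 1e-10)

  expect_error(fit_pseudotime_gam(pt[1:10], pt[1:10]), ">= 20",
               class = "anchortraj_validation_error")
  expect_error(fit_pseudotime_gam(pt, pt, df = 2), "df",
               class = "anchortraj_validation_error")
  expect_equal(nrow(perfect$grid), 100)
  expect_equal(range(perfect$grid$pseudotime), range(pt))
})

test_that("the anchor report flags the aberrant branch only", {
  sim <- cached_sim(1)
  model <- compute_pseudotime(
    infer_lineages(sim$dataset$embedding,
                   sim$dataset$cell_meta$cluster_label, "Transitional_AT2"),
    sim$dataset$embedding, sim$dataset$cell_meta$cluster_label)
  rep <- anchor_trajectory_report(sim$dataset, model, "IL11")
  expect_equal(nrow(rep$summary), 2)
  expect_true(rep$summary$flagged[rep$summary$terminus == "KRT5_KRT17"])
  expect_false(rep$summary$flagged[rep$summary$terminus == "AT1"])
  expect_gt(rep$summary$terminal_mean[rep$summary$terminus == "KRT5_KRT17"],
            rep$summary$terminal_mean[rep$summary$terminus == "AT1"])
  expect_error(anchor_trajectory_report(sim$dataset, model, "NOPE"),
               class = "anchortraj_validation_error")
})
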