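test_that("silhouette matches the hand-computed two-cluster example", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1L, 1L, 2L, 2L)
  expected <- ((10.5 - 1) / 10.5 + (9.5 - 1) / 9.5) / 2 # symmetric pairs
  expect_equal(silhouette_score(pts, lab), expected, tolerance = 1e-12)
  expect_equal(brute_silhouette(pts, lab), expected, tolerance = 1e-12)
})

test_that("silhouette of perfectly overlapped clusters is non-positive and bounded", {
  withr::with_seed(4, {
    x <- matrix(rnorm(60), ncol = 2)
    overlap <- rbind(x, x)
    lab <- rep(c(1L, 2L), each = 30)
    expect_lte(silhouette_score(overlap, lab), 0)
    for (i in 1:10) {
      inst <- random_metric_instance(1000 + i)
      s <- silhouette_score(inst$points, inst$labels)
      expect_gte(s, -1); expect_lte(s, 1)
    }
  })
})

test_that("dunn index matches brute force and behaves as the ratio demands", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1L, 1L, 2L, 2L)
  expect_equal(dunn_index(pts, lab), 9)
  # a bridging point can only shrink the numerator
  bridged <- rbind(pts, 5)
  expect_lt(dunn_index(bridged, c(lab, 2L)), 9)
  # scale invariance
  inst <- random_metric_instance(77)
  expect_equal(dunn_index(inst$points * 3.7, inst$labels),
               dunn_index(inst$points, inst$labels), tolerance = 1e-12)
})

test_that("both metrics agree with the O(n^2) brute-force oracles", {
  for (i in 1:12) {
    inst <- random_metric_instance(2000 + i)
    expect_equal(silhouette_score(inst$points, inst$labels),
                 brute_silhouette(inst$points, inst$labels), tolerance = 1e-9)
    expect_equal(dunn_index(inst$points, inst$labels),
                 brute_dunn(inst$points, inst$labels), tolerance = 1e-9)
  }
})

test_that("silhouette agrees with the cluster package implementation", {
  skip_if_not_installed("cluster")
  inst <- random_metric_instance(31)
  ref <- mean(cluster::silhouette(inst$labels, dist(inst$points))[, "sil_width"])
  expect_equal(silhouette_score(inst$points, inst$labels), ref, tolerance = 1e-9)
})

test_that("metrics exclude noise and refuse degenerate partitions", {
  pts <- matrix(c(0, 1, 10, 11, 100), ncol = 1)
  lab <- c(1L, 1L, 2L, 2L, -1L)
  expect_equal(dunn_index(pts, lab), 9) # the distant noise point is ignored
  expect_error(silhouette_score(pts, c(1L, 1L, 1L, 1L, -1L)), "two")
  expect_error(dunn_index(matrix(c(0, 0, 1, 1), ncol = 1), c(1L, 1L, 2L, 2L)),
               "diameters")
})

test_that("baselines produce the expected comparison table", {
  coh <- small_cohort()
  fit <- small_fit()
  weighted <- reweight_items(coh$items, fit$item_weights)
  bc <- baseline_compare(weighted, k_range = 2:4, seed = 7)
  expect_identical(nrow(bc), 6L) # 2 methods x 3 k
  expect_true(all(bc$silhouette >= -1 & bc$silhouette <= 1))
  expect_true(all(bc$dunn >= 0))
  # the density pipeline on its embedding outscores K-means on the raw items
  emb <- as.matrix(fit$embedding[c("u1", "u2")])
  pipeline_sil <- silhouette_score(emb, fit$assignment$pattern)
  raw_best <- max(baseline_compare(coh$items, k_range = 2:8, seed = 7,
                                   methods = "kmeans")$silhouette)
  expect_gt(pipeline_sil, raw_best)
})

test_that("grid search returns the argmax with a complete trace", {
  coh <- small_cohort()
  fit <- small_fit()
  weighted <- reweight_items(coh$items, fit$item_weights)
  gs <- grid_search_params(weighted, n_neighbors = c(20, 30),
                           min_pts = c(10, 17), seed = 42)
  expect_identical(nrow(gs$trace), 4L)
  best_score <- max(gs$trace$score, na.rm = TRUE)
  expect_equal(gs$best$score, best_score)
  # ties break toward smaller min_pts then smaller n_neighbors
  tied <- gs$trace[gs$trace$score == best_score, ]
  expect_identical(gs$best$min_pts, min(tied$min_pts))
  # degenerate single-point grid returns that point
  one <- grid_search_params(weighted, n_neighbors = 30, min_pts = 17, seed = 42)
  expect_identical(nrow(one$trace), 1L)
  expect_identical(one$best$n_neighbors, 30)
})
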