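test_that("item embedding uses z-scored patient vectors and flags constant items", {
  coh <- small_cohort()
  emb <- embed_items(coh$items, umap_params_items(seed = 1))
  expect_identical(nrow(emb), 16L)
  expect_named(emb, c("item", "u1", "u2"))
  const <- coh$items
  const$phq4 <- 2L
  expect_error(embed_items(const), "phq4")
})

test_that("duplicated item columns land on coincident embedded points", {
  coh <- small_cohort()
  dup <- coh$items
  dup$gad7 <- dup$gad1 # identical responses, identical z-columns
  emb <- embed_items(dup, umap_params_items(seed = 2))
  p1 <- as.numeric(emb[emb$item == "gad1", c("u1", "u2")])
  p2 <- as.numeric(emb[emb$item == "gad7", c("u1", "u2")])
  expect_lt(sqrt(sum((p1 - p2)^2)), 1e-8)
})

test_that("two blocks of perfectly correlated items give two clusters of eight", {
  withr::with_seed(5, {
    a <- sample(0:3, 400, replace = TRUE)
    b <- sample(0:3, 400, replace = TRUE)
  })
  items <- as.data.frame(c(
    setNames(rep(list(a), 8), psypatterns:::item_names()[1:8]),
    setNames(rep(list(b), 8), psypatterns:::item_names()[9:16])))
  emb <- embed_items(items, umap_params_items(seed = 3))
  cl <- cluster_items(emb)
  expect_identical(length(unique(cl$cluster)), 2L)
  expect_true(all(table(cl$cluster) == 8))
})

test_that("item weights are inverse cluster sizes, summing to one per cluster", {
  map <- tibble::tibble(
    item = psypatterns:::item_names(),
    cluster = rep(1:4, c(7, 4, 3, 2)))
  w <- compute_item_weights(map)
  expect_equal(unique(w$weight[w$cluster == 1]), 1 / 7)
  expect_equal(unique(w$weight[w$cluster == 2]), 1 / 4)
  expect_equal(unique(w$weight[w$cluster == 3]), 1 / 3)
  expect_equal(unique(w$weight[w$cluster == 4]), 1 / 2)
  sums <- tapply(w$weight, w$cluster, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # degenerate partitions
  one <- compute_item_weights(tibble::tibble(item = map$item, cluster = 1L))
  expect_true(all(one$weight == 1 / 16))
  singletons <- compute_item_weights(tibble::tibble(item = map$item, cluster = 1:16))
  expect_true(all(singletons$weight == 1))
})

test_that("reweighting multiplies columns and is invertible", {
  coh <- small_cohort()
  w1 <- setNames(rep(1, 16), psypatterns:::item_names())
  expect_equal(reweight_items(coh$items, w1)[psypatterns:::item_names()],
               coh$items[psypatterns:::item_names()], ignore_attr = TRUE)
  w <- w1; w["phq3"] <- 0.5
  half <- reweight_items(coh$items, w)
  expect_equal(half$phq3, coh$items$phq3 * 0.5)
  back <- reweight_items(half, 1 / w)
  expect_equal(as.matrix(back[psypatterns:::item_names()]),
               as.matrix(coh$items[psypatterns:::item_names()]) * 1.0,
               ignore_attr = TRUE)
  expect_error(reweight_items(coh$items, w[-1]), "missing weight")
})

test_that("small-cluster merging follows the nearest-centroid rule and terminates", {
  two_blob <- function(n1, n2, gap = 10) {
    tibble::tibble(patient_id = seq_len(n1 + n2),
                   u1 = c(rnorm(n1), rnorm(n2) + gap), u2 = rnorm(n1 + n2))
  }
  withr::with_seed(2, {
    emb <- two_blob(500, 150)
    asg <- tibble::tibble(patient_id = emb$patient_id,
                          pattern = rep(c(1L, 2L), c(500, 150)))
    merged <- merge_small_clusters(asg, emb, min_size = 200)
    expect_identical(sort(unique(merged$pattern)), 1L)
    expect_identical(sum(merged$pattern == 1L), 650L)

    # already-large clusters untouched
    asg_ok <- tibble::tibble(patient_id = emb$patient_id,
                             pattern = rep(c(1L, 2L), c(500, 150)))
    expect_identical(merge_small_clusters(asg_ok, emb, min_size = 100)$pattern,
                     asg_ok$pattern)

    # the undersized cluster merges into the nearer centroid
    emb3 <- tibble::tibble(
      patient_id = 1:950,
      u1 = c(rnorm(500), rnorm(300) + 20, rnorm(150) + 24), u2 = rnorm(950))
    asg3 <- tibble::tibble(patient_id = emb3$patient_id,
                           pattern = rep(c(1L, 2L, 3L), c(500, 300, 150)))
    merged3 <- merge_small_clusters(asg3, emb3, min_size = 200)
    sizes <- as.numeric(table(merged3$pattern))
    expect_identical(sort(sizes), c(450, 500))
    # the 150-cluster joined the 300-cluster, not the 500-cluster
    expect_identical(length(unique(merged3$pattern[751:950])), 1L)
    expect_identical(unique(merged3$pattern[751:950]),
                     unique(merged3$pattern[501:750]))
  })
  # noise is never merged
  asg_n <- tibble::tibble(patient_id = 1:300,
                          pattern = rep(c(1L, -1L), c(250, 50)))
  emb_n <- tibble::tibble(patient_id = 1:300, u1 = rnorm(300), u2 = rnorm(300))
  expect_identical(sum(merge_small_clusters(asg_n, emb_n, 100)$pattern == -1L), 50L)
})

test_that("profiles are raw-score means with sensible automatic names", {
  items <- small_cohort()$items
  asg <- tibble::tibble(patient_id = items$patient_id,
                        pattern = small_fit()$assignment$pattern)
  prof <- build_profiles(asg, items)
  m <- as.matrix(prof[psypatterns:::item_names()])
  expect_true(all(m >= 0 & m <= 3))
  expect_true("normal psychological functioning" %in% prof$name)
  expect_identical(sum(prof$size), sum(asg$pattern != -1L))
  # a pattern of all-zero responders profiles to zero and is the normal group
  zero_items <- items
  zero_items[psypatterns:::item_names()] <-
    lapply(zero_items[psypatterns:::item_names()], function(x) x * 0L)
  asg2 <- tibble::tibble(patient_id = items$patient_id,
                         pattern = rep(c(1L, 2L), length.out = nrow(items)))
  prof2 <- build_profiles(asg2, zero_items)
  expect_true(all(as.matrix(prof2[psypatterns:::item_names()]) == 0))
  expect_identical(prof2$name[1], "normal psychological functioning")
})

test_that("profile building is invariant to cluster relabeling", {
  coh <- small_cohort()
  fit <- small_fit()
  asg <- fit$assignment
  k <- max(asg$pattern)
  relab <- asg
  relab$pattern <- ifelse(asg$pattern == -1L, -1L, k + 1L - asg$pattern)
  p1 <- build_profiles(asg, coh$items)
  p2 <- build_profiles(relab, coh$items)
  expect_setequal(p1$name, p2$name)
  expect_identical(sort(p1$size), sort(p2$size))
})

test_that("the end-to-end pipeline runs on a small cohort and is deterministic", {
  fit <- small_fit()
  expect_s3_class(fit, "pattern_discovery")
  expect_identical(nrow(fit$assignment), 1500L)
  expect_identical(length(unique(fit$symptom_clusters$cluster)), 4L)
  g <- glance(fit)
  # at this cohort size the smallest planted class (~3%) may fall below the
  # scaled merge threshold; the contract is completion with a plausible
  # pattern count, not exact recovery
  expect_true(g$n_patterns %in% 4:7)
  fit2 <- run_discovery(small_cohort()$items, discovery_config(1500, seed = 42))
  expect_identical(fit$assignment, fit2$assignment)
  expect_identical(fit$profiles, fit2$profiles)
  td <- tidy(fit)
  expect_identical(nrow(td), nrow(fit$profiles))
  expect_lt(abs(sum(td$share) + g$noise_frac - 1), 1e-12)
})

test_that("stage errors are reported with the stage name", {
  coh <- small_cohort()
  cfg <- discovery_config(1500, seed = 1)
  cfg$stage2_hdbscan <- hdbscan_params(min_pts = 5000)
  expect_error(run_discovery(coh$items, cfg), "cluster_patients")
})
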