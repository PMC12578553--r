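test_that("the generator is deterministic for a fixed config", {
  a <- generate_item_responses(generator_config(n = 300, seed = 11))
  b <- generate_item_responses(generator_config(n = 300, seed = 11))
  expect_identical(a, b)
  expect_false(identical(
    a$items, generate_item_responses(generator_config(n = 300, seed = 12))$items))
  ca <- generate_covariates(generator_config(n = 300, seed = 11))
  cb <- generate_covariates(generator_config(n = 300, seed = 11))
  expect_identical(ca, cb)
})

test_that("every patient receives exactly one truth label from the spec set", {
  cfg <- generator_config(n = 500, seed = 3)
  ir <- generate_item_responses(cfg)
  expect_identical(nrow(ir$truth), 500L)
  expect_true(all(ir$truth$pattern %in% c(cfg$pattern_specs$pattern, "outlier")))
  m <- as.matrix(ir$items[-1])
  expect_true(all(m %in% 0:3))
  expect_false(anyNA(m))
})

test_that("class proportions and per-class item means match their targets at n = 10,000", {
  cfg <- cached("gen10k_cfg", generator_config(n = 10000, seed = 202))
  ir <- cached("gen10k", generate_item_responses(cfg))
  props <- table(ir$truth$pattern) / 10000
  spec_p <- setNames(cfg$pattern_specs$proportion, cfg$pattern_specs$pattern)
  for (cl in names(spec_p)) {
    expect_lt(abs(props[[cl]] - spec_p[[cl]]), 0.015)
  }
  expect_lt(abs(props[["outlier"]] - cfg$outlier_frac), 0.01)
  # discretization calibration: realized class means within +-0.1 of targets
  m <- as.matrix(ir$items[item_cols <- setdiff(names(ir$items), "patient_id")])
  for (cl in cfg$pattern_specs$pattern) {
    rows <- ir$truth$pattern == cl
    realized <- colMeans(m[rows, , drop = FALSE])
    targets <- as.numeric(cfg$pattern_specs[cfg$pattern_specs$pattern == cl, item_cols])
    expect_lt(max(abs(realized - targets)), 0.1)
  }
})

test_that("a single class with zero spread and zero means yields an all-zero matrix", {
  specs <- default_pattern_specs()[1, ]
  specs[psypatterns:::item_names()] <- 0
  specs$proportion <- 1
  cfg <- generator_config(n = 50, seed = 1, pattern_specs = specs,
                          outlier_frac = 0, within_class_sd = 0)
  ir <- generate_item_responses(cfg)
  expect_true(all(as.matrix(ir$items[-1]) == 0))
})

test_that("invalid generator configs are rejected", {
  bad <- default_pattern_specs()
  bad$phq1[1] <- 5
  expect_error(generator_config(pattern_specs = bad), "item_means")
  expect_error(generator_config(outlier_frac = 1.2), "outlier_frac")
  blocks <- default_item_blocks()
  expect_error(generator_config(item_blocks = blocks[-1]), "16 items")
})

test_that("covariate marginals are calibrated to the cohort table", {
  cov <- cached("cov10k", generate_covariates(generator_config(n = 10000, seed = 5)))
  expect_lt(abs(mean(cov$sex == "female") - 0.583), 0.02)
  expect_lt(abs(mean(cov$age) - 52.27), 0.5)
  expect_true(all(cov$age >= 40 & cov$age <= 65))
  expect_lt(abs(mean(cov$surgery_site == "abdomen") - 0.461), 0.02)
  expect_true(all(cov$cci >= 0 & cov$cci == round(cov$cci)))
  expect_true(all(cov$surgery_duration > 0))
})

test_that("with all effects zero, outcome prevalence is flat across classes", {
  cfg <- generator_config(n = 20000, seed = 9,
                          effect_spec = default_effect_spec()[0, ])
  ir <- cached("null_items", generate_item_responses(cfg))
  cov <- generate_covariates(cfg)
  out <- generate_outcomes(ir$truth, cov, cfg$effect_spec, seed = 9)
  prev <- tapply(out$any_complication, ir$truth$pattern, mean)
  prev <- prev[names(prev) != "outlier"]
  # Monte-Carlo noise: prevalences ~10% on groups of >= 600
  expect_lt(max(prev) - min(prev), 0.04)
  out2 <- generate_outcomes(ir$truth, cov, cfg$effect_spec, seed = 9)
  expect_identical(out, out2)
})

test_that("unknown outcomes or patterns in the effect spec are rejected", {
  coh <- small_cohort()
  bad <- tibble::tibble(outcome = "not_an_outcome", pattern = "normal", effect = 1)
  expect_error(generate_outcomes(coh$truth, coh$covariates, bad, 1), "unknown outcome")
  bad2 <- tibble::tibble(outcome = "infection", pattern = "no_such_class", effect = 1)
  expect_error(generate_outcomes(coh$truth, coh$covariates, bad2, 1), "unknown pattern")
})

test_that("simulated cohorts are row-aligned with cut-off status attached", {
  coh <- small_cohort()
  expect_identical(coh$items$patient_id, coh$covariates$patient_id)
  expect_identical(coh$items$patient_id, coh$outcomes$patient_id)
  expect_identical(coh$items$patient_id, coh$truth$patient_id)
  phq <- score_scale(coh$items, "PHQ9")
  gad <- score_scale(coh$items, "GAD7")
  expect_identical(coh$truth$cutoff_positive, classify_cutoff(phq, gad))
})
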