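# direct maximum-likelihood logistic fit, independent of glm, for the oracle
optim_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- X %*% b
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(b) t(X) %*% (1 / (1 + exp(-X %*% b)) - y)
  optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}

test_that("the logistic fit agrees with an independent optimiser", {
  d <- analysis_table()
  d <- d[!is.na(d$pattern), ]
  # centre and scale the continuous covariates so the independent optimiser
  # works on a well-conditioned problem
  d$age_z <- as.numeric(scale(d$age))
  d$bmi_z <- as.numeric(scale(d$bmi))
  res <- fit_binary(d, "any_complication", covariates = c("age_z", "bmi_z"))
  X <- stats::model.matrix(~ pattern + age_z + bmi_z, d)
  b <- optim_logistic(X, d$any_complication)
  ors <- exp(b[grepl("pattern", colnames(X))])
  expect_equal(res$estimate, unname(ors), tolerance = 1e-6)
})

test_that("the linear fit agrees with the normal equations", {
  d <- analysis_table()
  d <- d[!is.na(d$pattern), ]
  d$pain <- standardize_0_10(d$pain_rest_d1, 0, 10)
  res <- fit_linear(d, "pain", covariates = c("age", "bmi"))
  X <- stats::model.matrix(~ pattern + age + bmi, d)
  b <- solve(crossprod(X), crossprod(X, d$pain))
  expect_equal(res$estimate, unname(b[grepl("pattern", rownames(b)), 1]),
               tolerance = 1e-9)
})

test_that("a planted odds ratio is recovered by the adjusted logistic model", {
  es <- tibble::tibble(outcome = "any_complication", pattern = "combined",
                       effect = log(1.3))
  cfg <- generator_config(n = 20000, seed = 15, outlier_frac = 0, effect_spec = es)
  coh <- cached("planted_coh", simulate_cohort(n = 20000, seed = 15, config = cfg))
  d <- dplyr::left_join(coh$covariates, coh$outcomes, by = "patient_id")
  d$pattern <- factor(coh$truth$pattern,
                      levels = c("normal", setdiff(unique(coh$truth$pattern), "normal")))
  res <- fit_binary(d, "any_complication")
  row <- res[res$exposure_level == "combined", ]
  expect_true(row$ci_low <= 1.3 && 1.3 <= row$ci_high)
  expect_lt(abs(log(row$estimate) - log(1.3)), 0.2)
})

test_that("a planted slope is recovered and is standardization-invariant", {
  es <- tibble::tibble(outcome = "pain_rest", pattern = "combined", effect = 0.4)
  cfg <- generator_config(n = 20000, seed = 16, outlier_frac = 0, effect_spec = es)
  coh <- simulate_cohort(n = 20000, seed = 16, config = cfg)
  d <- dplyr::left_join(coh$covariates, coh$outcomes, by = "patient_id")
  d$pattern <- factor(coh$truth$pattern,
                      levels = c("normal", setdiff(unique(coh$truth$pattern), "normal")))
  d$y <- standardize_0_10(d$pain_rest_d1, 0, 10)
  res <- fit_linear(d, "y")
  row <- res[res$exposure_level == "combined", ]
  expect_true(row$ci_low <= 0.4 && 0.4 <= row$ci_high)
  # doubling the native scale and re-standardizing changes nothing
  d$y2 <- standardize_0_10(2 * d$pain_rest_d1, 0, 20)
  res2 <- fit_linear(d, "y2")
  expect_equal(res2$estimate, res$estimate, tolerance = 1e-9)
})

test_that("degenerate outcomes and exposures are refused loudly", {
  d <- analysis_table()
  d$const <- 1L
  expect_error(fit_binary(d, "const"), "constant")
  d$pattern2 <- factor("only_level")
  expect_error(fit_binary(d, "any_complication", exposure = "pattern2"), "levels")
})

test_that("baseline-condition exclusions hit only the matching outcome families", {
  d <- analysis_table()
  ex <- apply_exclusions(d, "cognitive")
  expect_identical(ex$n_excluded, sum(d$baseline_cognitive_dysfunction))
  expect_identical(nrow(ex$data) + ex$n_excluded, nrow(d))
  ex2 <- apply_exclusions(d, "memory")
  expect_identical(ex2$n_excluded, sum(d$baseline_memory_deterioration))
  none <- apply_exclusions(d, "sleep")
  expect_identical(none$n_excluded, 0L)
  expect_identical(nrow(none$data), nrow(d))
  d2 <- d[setdiff(names(d), "baseline_cognitive_dysfunction")]
  expect_error(apply_exclusions(d2, "cognitive"), "baseline")
})

test_that("the association suite covers the full outcome grid with bookkeeping", {
  d <- analysis_table()
  forest <- cached("forest_small", run_association_suite(d))
  reg <- outcome_registry()
  n_models <- sum(vapply(reg$timepoints, function(t) max(length(t), 1L), integer(1)))
  k_patterns <- nlevels(d$pattern)
  expected_rows <- n_models * ((k_patterns - 1) + 1) # patterns + cut-off
  expect_identical(nrow(forest), as.integer(expected_rows))
  expect_true(all(!is.na(forest$estimate)))
  ok <- !is.na(forest$estimate)
  expect_true(all(forest$ci_low[ok] <= forest$estimate[ok] &
                    forest$estimate[ok] <= forest$ci_high[ok]))
  expect_true(all(forest$estimate[forest$effect_type == "OR" & ok] > 0))
  # accounting: used + excluded + baseline-excluded + noise = cohort
  expect_true(all(forest$n_used + forest$n_excluded +
                    forest$n_baseline_excluded + forest$n_noise == nrow(d)))
  expect_true(all(forest$n_noise == sum(is.na(d$pattern))))
  # anesthesia type only adjusts the discomfort models: its absence breaks them
  d_no_anes <- d[setdiff(names(d), "anesthesia_type")]
  f2 <- run_association_suite(d_no_anes)
  bad <- f2[f2$outcome %in% c("pain_rest", "pain_move", "nausea"), ]
  expect_true(all(grepl("anesthesia_type", bad$note)))
  good <- f2[f2$outcome == "any_complication", ]
  expect_true(all(is.na(good$note)))
})

test_that("rerunning the suite reproduces the identical table", {
  d <- analysis_table()
  expect_identical(run_association_suite(d), run_association_suite(d))
})

test_that("surgery-site subgroups are fitted per stratum, small strata skipped", {
  d <- analysis_table()
  sub <- suppressWarnings(subgroup_analyses(
    d, min_n = 100, exposures = "pattern"))
  expect_setequal(unique(sub$subgroup), unique(d$surgery_site))
  # one-patient stratum is skipped with a warning
  d2 <- d
  d2$surgery_site[1] <- "rare_site"
  w <- capture_warnings(subgroup_analyses(d2[d2$surgery_site == "rare_site" |
                                               seq_len(nrow(d2)) <= 50, ],
                                          min_n = 30, exposures = "pattern"))
  expect_true(any(grepl("rare_site.*skipped", w)))
})
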