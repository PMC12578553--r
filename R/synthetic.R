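#' Default latent psychological profiles
#'
#' Six latent classes calibrated to the published pattern structure: a
#' "normal psychological functioning" majority (32.6%) and five distress
#' classes — "sleep and eating disturbance" (13.2%), "sleep disturbance and
#' irritability" (3.2%), "nervousness" (14.0%), "nervousness, sleep
#' disturbance, and excessive worry" (8.1%) and "highly combined symptoms"
#' (26.6%) — with a 2.2% outlier fraction alongside. Published sources give
#' per-pattern item profiles only graphically, so the mean item-score vectors
#' are schematic: the pattern-defining items are set high (2-2.7), secondary
#' items intermediate, and the remainder low.
#'
#' @return A tibble with one row per class: `pattern`, `proportion` and the
#'   16 target mean item scores (`phq1`..`gad7`).
#' @export
default_pattern_specs <- function() {
  blocks <- default_item_blocks()
  level <- function(dep, worry, sleep, tension) {
    setNames(c(dep, worry, sleep, tension)[blocks], names(blocks))
  }
  m <- rbind(
    # block levels: depressive core, worry, sleep/somatic, tension
    normal        = level(0.40, 0.40, 0.45, 0.35),
    sleep_eating  = level(0.60, 0.50, 2.60, 0.45),
    sleep_irrit   = level(0.60, 0.55, 1.60, 2.70),
    nervous       = level(0.50, 2.50, 0.50, 0.70),
    nervous_sleep_worry = level(0.50, 2.90, 2.70, 1.20),
    combined      = level(2.20, 2.10, 2.20, 2.10)
  )
  out <- as_tibble(m)
  out$pattern <- rownames(m)
  out$proportion <- c(.326, .132, .032, .140, .081, .266)
  select(out, "pattern", "proportion", all_of(item_names()))
}

#' Default partition of the 16 items into symptom blocks
#'
#' Four blocks of varying size, mirroring the published four-symptom-cluster
#' structure: a depressive core (anhedonia, depressed mood, worthlessness,
#' concentration, suicidality), a worry/nervousness block, a sleep/somatic
#' block (sleep, fatigue, appetite, psychomotor change) and a
#' tension/irritability block. Within-block latent correlation is what makes
#' item-level clustering meaningful.
#'
#' @return Named integer vector mapping each item to a block id 1..4.
#' @export
default_item_blocks <- function() {
  setNames(c(1L, 1L, 3L, 3L, 3L, 1L, 1L, 3L, 1L,   # phq1..phq9
             2L, 2L, 2L, 4L, 4L, 4L, 2L),          # gad1..gad7
           item_names())
}

#' Generator configuration
#'
#' Bundles everything the synthetic-cohort generator needs. Defaults are the
#' calibrated study conditions: the six-class mixture of
#' [default_pattern_specs()], a 2.2% outlier fraction, four latent symptom
#' blocks with within-block correlation 0.6 and between-block correlation
#' 0.1, and Bernoulli/Gaussian outcome models with the planted effects of
#' [default_effect_spec()]. Mixing proportions are normalised so that, with
#' the outlier fraction, they sum to one.
#'
#' @param n Cohort size.
#' @param seed Integer master seed; per-stage child seeds are derived from it.
#' @param pattern_specs Tibble as returned by [default_pattern_specs()].
#' @param outlier_frac Fraction of patients drawn uniformly over the item
#'   hypercube (in `[0, 1)`).
#' @param item_blocks Named integer vector partitioning the 16 items.
#' @param rho_within,rho_between Latent correlations within/between blocks.
#' @param rho_hub Latent correlation between each block's core item (the
#'   first item of the block) and the block's other members. Each symptom
#'   block has one core defining symptom that co-varies most strongly with
#'   the rest of the block — a hub topology that keeps the block's
#'   nearest-neighbour structure connected, as in real instruments where one
#'   cardinal symptom anchors each cluster.
#' @param within_class_sd Latent marginal standard deviation per item.
#' @param thresholds Latent cut points mapping the Gaussian to scores 0..3.
#' @param effect_spec Planted pattern-by-outcome effects, see
#'   [default_effect_spec()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n = 10000, seed = 1L,
                             pattern_specs = default_pattern_specs(),
                             outlier_frac = 0.022,
                             item_blocks = default_item_blocks(),
                             rho_within = 0.6, rho_between = 0.1,
                             rho_hub = 0.78,
                             within_class_sd = 0.6,
                             thresholds = c(0.5, 1.5, 2.5),
                             effect_spec = default_effect_spec()) {
  if (outlier_frac < 0 || outlier_frac >= 1) abort("outlier_frac must be in [0, 1)")
  mm <- as.matrix(pattern_specs[item_names()])
  if (any(mm < 0 | mm > 3)) abort("item_means must lie in [0, 3]")
  if (any(pattern_specs$proportion <= 0)) abort("mixing proportions must be positive")
  if (!setequal(names(item_blocks), item_names())) {
    abort("item_blocks must cover exactly the 16 items")
  }
  ps <- pattern_specs
  ps$proportion <- ps$proportion / sum(ps$proportion) * (1 - outlier_frac)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 pattern_specs = ps, outlier_frac = outlier_frac,
                 item_blocks = item_blocks[item_names()],
                 rho_within = rho_within, rho_between = rho_between,
                 rho_hub = rho_hub,
                 within_class_sd = within_class_sd, thresholds = thresholds,
                 effect_spec = effect_spec),
            class = "generator_config")
}

# Latent mean per item per class so that the expected discretised score
# matches the target. E[score] = sum_t pnorm((mu - t) / sd) is monotone in mu,
# solved by root finding; in the degenerate sd -> 0 limit the latent equals
# the target itself.
solve_latent_means <- function(targets, thresholds, sd) {
  if (sd < 1e-6) return(targets)
  vapply(targets, function(tg) {
    f <- function(mu) sum(pnorm((mu - thresholds) / sd)) - tg
    uniroot(f, c(-10, 13), tol = 1e-10)$root
  }, numeric(1))
}

#' Generate item responses and truth labels
#'
#' Draws a latent class for each patient from the mixing proportions, then a
#' 16-dimensional latent Gaussian with the configured block-correlation
#' structure, discretised to 0..3 at fixed thresholds whose per-class latent
#' means are solved numerically so realized class means match the targets
#' (graded-response-style generation). Outliers are i.i.d. uniform on
#' `{0,..,3}^16` — the simplest model of patients belonging to no pattern.
#' Fully reproducible for a given config.
#'
#' @param config A [generator_config()].
#' @return A list with `items` (tibble: `patient_id` + 16 item columns) and
#'   `truth` (tibble: `patient_id`, `pattern`, with `"outlier"` for planted
#'   outliers).
#' @export
generate_item_responses <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ps <- config$pattern_specs
  n <- config$n
  blocks <- config$item_blocks
  same_block <- outer(blocks, blocks, "==")
  R <- ifelse(same_block, config$rho_within, config$rho_between)
  # hub topology: the first item of each block is its core symptom and
  # correlates rho_hub with every other member
  is_hub <- !duplicated(blocks)
  hub_pair <- same_block & (outer(is_hub, is_hub, "|"))
  R[hub_pair] <- config$rho_hub
  diag(R) <- 1
  Sigma <- R * config$within_class_sd^2

  withr::with_seed(derive_seed(config$seed, 1L), {
    labels <- sample(c(ps$pattern, "outlier"), n, replace = TRUE,
                     prob = c(ps$proportion, config$outlier_frac))
    items <- matrix(0L, n, 16, dimnames = list(NULL, item_names()))
    for (cl in ps$pattern) {
      rows <- which(labels == cl)
      if (!length(rows)) next
      targets <- as.numeric(ps[ps$pattern == cl, item_names()])
      mu <- solve_latent_means(targets, config$thresholds, config$within_class_sd)
      lat <- if (config$within_class_sd < 1e-6) {
        matrix(mu, length(rows), 16, byrow = TRUE)
      } else {
        MASS::mvrnorm(length(rows), mu, Sigma)
      }
      items[rows, ] <- matrix(findInterval(lat, config$thresholds), length(rows))
    }
    out_rows <- which(labels == "outlier")
    if (length(out_rows)) {
      # Outliers are micro-groups of patients sharing a rare idiosyncratic
      # symptom combination, scattered uniformly over the latent item space.
      # Isolated single atypical responders are pulled into the nearest
      # pattern by any neighbourhood-based method (the embedding guarantees
      # local connectivity); what density clustering can and does flag as
      # noise are atypical groups large enough to form their own low-density
      # island yet below the minimum cluster size. Group sizes are drawn as
      # 0.28%-0.40% of the cohort: at least the embedding neighbourhood size
      # (so a group's neighbour lists are self-contained) while even two
      # co-located groups stay below the scaled minimum cluster size
      # (~0.84% of the cohort) instead of fusing into a spurious pattern.
      n_out <- length(out_rows)
      sizes <- integer(0)
      while (sum(sizes) < n_out) {
        sizes <- c(sizes, max(2L, as.integer(round(n * runif(1, 0.0028, 0.0040)))))
      }
      sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_out)
      sizes <- sizes[sizes > 0]
      rogue <- matrix(0L, 0, 16)
      for (sz in sizes) {
        centre <- runif(16, -0.5, 3.5)
        lat <- matrix(rnorm(sz * 16, mean = rep(centre, each = sz), sd = 0.3), sz)
        rogue <- rbind(rogue, matrix(findInterval(lat, config$thresholds), sz))
      }
      items[out_rows, ] <- rogue
    }
    list(items = bind_cols(tibble(patient_id = seq_len(n)), as_tibble(items)),
         truth = tibble(patient_id = seq_len(n), pattern = labels))
  })
}

#' Generate baseline covariates
#'
#' Independent draws per covariate from marginals calibrated to the study
#' cohort: age truncated-normal 52.3 (SD 7.1) on 40-65 years, 58.3% female,
#' BMI normal around 23.8 kg/m2, Poisson comorbidity index, and categorical
#' marginals for education, smoking (including a 0.1% "unknown" level),
#' alcohol, surgery site, anesthesia type, with log-normal surgery duration
#' in minutes. Covariates are independent of the latent class by default.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per patient.
#' @export
generate_covariates <- function(config) {
  n <- config$n
  withr::with_seed(derive_seed(config$seed, 2L), {
    zlo <- pnorm((40 - 52.27) / 7.07)
    zhi <- pnorm((65 - 52.27) / 7.07)
    tibble(
      patient_id = seq_len(n),
      age = 52.27 + 7.07 * qnorm(runif(n, zlo, zhi)),
      sex = sample(c("female", "male"), n, TRUE, prob = c(.583, .417)),
      education = sample(c("elementary_or_lower", "junior_school",
                           "senior_secondary", "college_or_above"),
                         n, TRUE, prob = c(.030, .252, .219, .499)),
      bmi = rnorm(n, 23.8, 3.0),
      cci = rpois(n, 0.45),
      smoking = sample(c("never", "previous", "current", "unknown"),
                       n, TRUE, prob = c(.733, .083, .183, .001)),
      alcohol = sample(c("no", "yes"), n, TRUE, prob = c(.819, .181)),
      surgery_site = sample(c("abdomen", "head_neck", "thorax", "others"),
                            n, TRUE, prob = c(.461, .206, .151, .182)),
      surgery_duration = pmin(pmax(rlnorm(n, log(90), 0.6), 15), 600),
      anesthesia_type = sample(c("combined_iv_inhalation", "total_iv",
                                 "inhalation"),
                               n, TRUE, prob = c(.947, .045, .008))
    )
  })
}

#' Default planted pattern-by-outcome effects
#'
#' Log odds ratios (binary outcomes) and slopes on the outcome's native scale
#' (continuous outcomes), per distress pattern, with magnitudes informed by
#' the published association ranges (complication ORs around 1.2-1.3, sleep
#' disturbance ORs up to ~3, recovery and satisfaction slopes a fraction of a
#' point). Pattern-outcome pairs not listed default to zero.
#'
#' @return A tibble with columns `outcome`, `pattern`, `effect`.
#' @export
default_effect_spec <- function() {
  distress <- c("sleep_eating", "sleep_irrit", "nervous",
                "nervous_sleep_worry", "combined")
  bind_rows(
    tibble(outcome = "any_complication", pattern = distress,
           effect = log(c(1.25, 1.10, 1.33, 1.30, 1.24))),
    tibble(outcome = "pulmonary_complication", pattern = distress,
           effect = log(c(1.20, 1.08, 1.25, 1.22, 1.20))),
    tibble(outcome = "infection", pattern = distress,
           effect = log(c(1.15, 1.05, 1.20, 1.18, 1.15))),
    tibble(outcome = "cognitive_dysfunction", pattern = distress,
           effect = log(c(1.35, 2.50, 1.40, 1.45, 1.40))),
    tibble(outcome = "memory_deterioration", pattern = distress,
           effect = log(c(1.00, 1.00, 1.20, 1.05, 1.30))),
    tibble(outcome = "sleep_disturbance", pattern = distress,
           effect = log(c(1.80, 2.20, 1.50, 2.00, 3.00))),
    tibble(outcome = "los_days", pattern = distress,
           effect = c(.35, .10, .30, .15, .40)),
    tibble(outcome = "pain_rest", pattern = distress,
           effect = c(.15, .30, .15, .45, .50)),
    tibble(outcome = "pain_move", pattern = distress,
           effect = c(.15, .30, .15, .45, .55)),
    tibble(outcome = "nausea", pattern = distress,
           effect = c(.10, .25, .10, .35, .40)),
    tibble(outcome = "recovery", pattern = distress,
           effect = c(-.20, -.20, -.20, -.25, -.40)),
    tibble(outcome = "life_satisfaction", pattern = distress,
           effect = c(-.06, -.08, -.06, -.08, -.12))
  )
}

# baseline levels of each outcome for the reference class; binary values are
# prevalences (intercept on the logit scale), continuous are means on the
# native scale with the given residual SD
outcome_baselines <- function() {
  list(
    binary = c(any_complication = .10, pulmonary_complication = .08,
               infection = .055,
               cognitive_dysfunction_m1 = .05, cognitive_dysfunction_m6 = .04,
               cognitive_dysfunction_m12 = .035,
               memory_deterioration_m1 = .08, memory_deterioration_m6 = .07,
               memory_deterioration_m12 = .06,
               sleep_disturbance_m1 = .25, sleep_disturbance_m6 = .22,
               sleep_disturbance_m12 = .20),
    continuous = c(los_days = 4.1,
                   pain_rest_d1 = 3.5, pain_rest_d3 = 2.2,
                   pain_move_d1 = 4.2, pain_move_d3 = 2.9,
                   nausea_d1 = 1.8, nausea_d3 = 1.0,
                   recovery_m1 = 7.0, recovery_m6 = 7.8, recovery_m12 = 8.2,
                   life_satisfaction_m1 = 3.0, life_satisfaction_m6 = 3.05,
                   life_satisfaction_m12 = 3.1),
    sigma = c(los_days = 3.0, pain_rest = 1.5, pain_move = 1.6, nausea = 1.4,
              recovery = 1.5, life_satisfaction = 0.8)
  )
}

# modest covariate effects shared by all outcome models (log-odds / native
# units); age, bmi, duration are centred so intercepts keep their meaning
covariate_linpred <- function(cov, scale = 1) {
  scale * (0.015 * (cov$age - 52) +
           0.10 * (cov$sex == "female") +
           0.012 * (cov$bmi - 24) +
           0.15 * pmin(cov$cci, 6) +
           0.002 * (cov$surgery_duration - 100) +
           0.12 * (cov$smoking == "current") +
           0.05 * (cov$alcohol == "yes") +
           0.10 * (cov$surgery_site == "thorax") -
           0.05 * (cov$surgery_site == "head_neck") +
           0.04 * (cov$education == "elementary_or_lower"))
}

#' Generate outcomes with planted pattern effects
#'
#' Binary outcomes are Bernoulli draws from a logistic model
#' (intercept from the configured baseline prevalence + planted pattern
#' effect + modest covariate effects); continuous outcomes are Gaussian
#' around the analogous linear predictor, clipped to the outcome's native
#' range. Baseline cognitive-dysfunction and memory-deterioration flags are
#' also drawn so exclusion rules can be exercised downstream.
#'
#' @param truth Truth tibble from [generate_item_responses()].
#' @param covariates Tibble from [generate_covariates()].
#' @param effect_spec Tibble (`outcome`, `pattern`, `effect`); unknown outcome
#'   or pattern names are an error.
#' @param seed Integer seed.
#' @return A tibble with one row per patient and one column per
#'   outcome-timepoint.
#' @export
generate_outcomes <- function(truth, covariates, effect_spec = default_effect_spec(),
                              seed = 1L) {
  reg <- outcome_registry()
  bad_out <- setdiff(unique(effect_spec$outcome), reg$name)
  if (length(bad_out)) abort(paste0("unknown outcome in effect_spec: ",
                                    paste(bad_out, collapse = ", ")))
  known_patterns <- c(unique(truth$pattern), "outlier")
  bad_pat <- setdiff(unique(effect_spec$pattern), known_patterns)
  if (length(bad_pat)) abort(paste0("unknown pattern in effect_spec: ",
                                    paste(bad_pat, collapse = ", ")))
  n <- nrow(truth)
  base <- outcome_baselines()

  effect_for <- function(outcome) {
    es <- effect_spec[effect_spec$outcome == outcome, ]
    eff <- setNames(rep(0, length(known_patterns)), known_patterns)
    eff[es$pattern] <- es$effect
    eff[truth$pattern]
  }

  withr::with_seed(derive_seed(seed, 3L), {
    out <- tibble(patient_id = truth$patient_id)
    for (i in seq_len(nrow(reg))) {
      nm <- reg$name[i]
      tps <- reg$timepoints[[i]]
      cols <- if (length(tps)) paste(nm, tps, sep = "_") else nm
      for (col in cols) {
        if (reg$type[i] == "binary") {
          p0 <- if (col %in% names(base$binary)) base$binary[[col]] else base$binary[[nm]]
          lp <- log(p0 / (1 - p0)) + effect_for(nm) + covariate_linpred(covariates)
          out[[col]] <- rbinom(n, 1, 1 / (1 + exp(-lp)))
        } else {
          mu0 <- if (col %in% names(base$continuous)) base$continuous[[col]] else base$continuous[[nm]]
          sgn <- if (reg$adverse_high[i]) 1 else -1
          lp <- mu0 + effect_for(nm) + sgn * 0.3 * covariate_linpred(covariates)
          y <- rnorm(n, lp, base$sigma[[nm]])
          lo <- reg$range_min[i]
          hi <- reg$range_max[i]
          if (is.finite(lo)) y <- pmax(y, lo)
          if (!is.na(hi)) y <- pmin(y, hi)
          out[[col]] <- y
        }
      }
    }
    out$baseline_cognitive_dysfunction <- rbinom(n, 1, .03) == 1
    out$baseline_memory_deterioration <- rbinom(n, 1, .05) == 1
    out
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs the three generator stages (items + truth, covariates, outcomes) off
#' one master seed and returns them row-aligned, together with the cut-off
#' symptom status computed from the generated items.
#'
#' @param n Cohort size.
#' @param seed Integer master seed.
#' @param config Optional [generator_config()]; `n` and `seed` override its
#'   fields when given.
#' @return An object of class `psy_cohort`: a list with tibbles `items`,
#'   `covariates`, `outcomes`, `truth`, and the `config` used.
#' @export
#' @examples
#' coh <- simulate_cohort(n = 300, seed = 7)
#' table(coh$truth$pattern)
simulate_cohort <- function(n = 10000, seed = 1L, config = NULL) {
  if (is.null(config)) {
    config <- generator_config(n = n, seed = seed)
  } else {
    config$n <- as.integer(n)
    config$seed <- as.integer(seed)
  }
  ir <- generate_item_responses(config)
  cov <- generate_covariates(config)
  outc <- generate_outcomes(ir$truth, cov, config$effect_spec, config$seed)
  phq <- score_scale(ir$items, "PHQ9")
  gad <- score_scale(ir$items, "GAD7")
  ir$truth$cutoff_positive <- classify_cutoff(phq, gad)
  structure(list(items = ir$items, covariates = cov, outcomes = outc,
                 truth = ir$truth, config = config),
            class = "psy_cohort")
}

#' @export
print.psy_cohort <- function(x, ...) {
  cat("Synthetic surgical cohort:", nrow(x$items), "patients\n")
  cat("  latent classes:", paste(sort(unique(x$truth$pattern)), collapse = ", "), "\n")
  cat("  outliers:", sum(x$truth$pattern == "outlier"),
      sprintf("(%.1f%%)", 100 * mean(x$truth$pattern == "outlier")), "\n")
  cat("  cut-off symptom-positive:",
      sprintf("%.1f%%", 100 * mean(x$truth$cutoff_positive)), "\n")
  invisible(x)
}
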