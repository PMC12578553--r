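#' Default covariate adjustment set
#'
#' Age (continuous), sex, education, BMI (continuous), Charlson comorbidity
#' index (continuous), smoking status, current alcohol consumption, surgery
#' site, and surgery duration (continuous) — the adjustment used by every
#' association model; anesthesia-related discomfort models add anesthesia
#' type.
#'
#' @return Character vector of covariate column names.
#' @export
default_adjustment <- function() {
  c("age", "sex", "education", "bmi", "cci", "smoking", "alcohol",
    "surgery_site", "surgery_duration")
}

#' Assemble the analysis table
#'
#' Joins covariates, outcomes, the pattern assignment and the cut-off symptom
#' status into one modelling tibble. Patterns are labeled by their profile
#' names, with the reference level set to the pattern named "normal
#' psychological functioning" (or, failing that, the pattern with the lowest
#' mean total score); noise patients carry `NA` and are dropped by the models
#' with a logged count.
#'
#' @param cohort A `psy_cohort` from [simulate_cohort()] (or a list with
#'   `items`, `covariates`, `outcomes` tibbles sharing `patient_id`).
#' @param fit A `pattern_discovery` object, or an assignment tibble plus
#'   `profiles`.
#' @param profiles Profile tibble when `fit` is a bare assignment.
#' @return A tibble with one row per patient; attribute `"reference"` names
#'   the reference pattern level.
#' @export
assemble_analysis_table <- function(cohort, fit, profiles = NULL) {
  if (inherits(fit, "pattern_discovery")) {
    assignment <- fit$assignment
    profiles <- fit$profiles
  } else {
    assignment <- fit
    if (is.null(profiles)) abort("profiles required with a bare assignment")
  }
  ref_row <- which(profiles$name == "normal psychological functioning")
  if (!length(ref_row)) ref_row <- which.min(rowSums(as.matrix(profiles[item_names()])))
  lev <- profiles$name[order(profiles$pattern)]
  pattern_name <- setNames(profiles$name, profiles$pattern)

  phq <- score_scale(cohort$items, "PHQ9")
  gad <- score_scale(cohort$items, "GAD7")
  out <- cohort$covariates |>
    left_join(cohort$outcomes, by = "patient_id") |>
    mutate(
      pattern = factor(
        ifelse(assignment$pattern == NOISE_LABEL, NA_character_,
               pattern_name[as.character(assignment$pattern)]),
        levels = c(profiles$name[ref_row[1]],
                   setdiff(lev, profiles$name[ref_row[1]]))),
      cutoff_status = factor(ifelse(classify_cutoff(phq, gad),
                                    "positive", "negative"),
                             levels = c("negative", "positive")))
  attr(out, "reference") <- profiles$name[ref_row[1]]
  attr(out, "n_noise") <- sum(assignment$pattern == NOISE_LABEL)
  out
}

# shared model-fitting core for the two families
fit_model <- function(data, outcome, exposure, covariates, family) {
  needed <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  n_total <- nrow(data)
  # listwise drops: unknown categorical levels, missing exposure (noise), NAs
  for (col in covariates) {
    if (is.character(data[[col]]) || is.factor(data[[col]])) {
      data[[col]][data[[col]] == "unknown"] <- NA
    }
  }
  cc <- complete.cases(data[needed])
  data <- data[cc, , drop = FALSE]
  if (is.factor(data[[exposure]])) data[[exposure]] <- droplevels(data[[exposure]])
  y <- data[[outcome]]
  if (length(unique(y)) < 2) {
    abort(paste0("outcome '", outcome, "' is constant; no model fit"))
  }
  if (length(unique(data[[exposure]])) < 2) {
    abort(paste0("exposure '", exposure, "' has fewer than two observed levels"))
  }
  fml <- as.formula(paste(outcome, "~", paste(c(exposure, covariates), collapse = " + ")))
  notes <- character(0)
  fit <- withCallingHandlers(
    if (family == "binomial") glm(fml, data = data, family = binomial())
    else lm(fml, data = data),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (family == "binomial" && !fit$converged) notes <- c(notes, "did not converge")
  b <- coef(fit)
  if (anyNA(b)) {
    abort(paste0("rank-deficient design; collinear terms: ",
                 paste(names(b)[is.na(b)], collapse = ", ")))
  }
  se <- sqrt(diag(vcov(fit)))
  keep <- grepl(paste0("^", exposure), names(b))
  levels_ <- sub(paste0("^", exposure), "", names(b)[keep])
  est <- unname(b[keep]); s <- unname(se[keep])
  z <- est / s
  p <- 2 * pnorm(-abs(z))
  tibble(
    exposure_level = levels_,
    effect_type = if (family == "binomial") "OR" else "beta",
    estimate = if (family == "binomial") exp(est) else est,
    ci_low = if (family == "binomial") exp(est - 1.959964 * s) else est - 1.959964 * s,
    ci_high = if (family == "binomial") exp(est + 1.959964 * s) else est + 1.959964 * s,
    p = p,
    n_used = nrow(data),
    n_excluded = n_total - nrow(data),
    note = if (length(notes)) paste(unique(notes), collapse = "; ") else NA_character_)
}

#' Adjusted logistic model for a binary outcome
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' categorical exposure (patterns or cut-off status, against its reference
#' level) with the standard covariate adjustment; Wald 95% confidence
#' intervals on the odds-ratio scale, one row per non-reference exposure
#' level. Non-convergence or separation is flagged in `note`, never silently
#' dropped; a constant outcome is an error.
#'
#' @param data Analysis tibble from [assemble_analysis_table()].
#' @param outcome Binary outcome column name.
#' @param exposure Exposure column name (`"pattern"` or `"cutoff_status"`).
#' @param covariates Adjustment set.
#' @return A tibble with `exposure_level`, `estimate` (OR), `ci_low`,
#'   `ci_high`, `p`, `n_used`, `n_excluded`, `note`.
#' @export
fit_binary <- function(data, outcome, exposure = "pattern",
                       covariates = default_adjustment()) {
  fit_model(data, outcome, exposure, covariates, "binomial")
}

#' Adjusted linear model for a continuous outcome
#'
#' Ordinary least squares with the same adjustment set; slopes with Wald 95%
#' confidence intervals per exposure level. The outcome should already be on
#' the 0-10 analysis scale (see [standardize_0_10()]); length of stay is
#' conventionally modeled on its raw day scale.
#'
#' @inheritParams fit_binary
#' @return A tibble as in [fit_binary()] with `effect_type = "beta"`.
#' @export
fit_linear <- function(data, outcome, exposure = "pattern",
                       covariates = default_adjustment()) {
  fit_model(data, outcome, exposure, covariates, "gaussian")
}

#' Baseline-condition exclusions
#'
#' For the cognitive-dysfunction and memory-deterioration outcome families
#' only, patients already positive for the condition before surgery are
#' excluded from the corresponding models; other outcome families use the
#' full cohort.
#'
#' @param data Analysis tibble carrying `baseline_cognitive_dysfunction` and
#'   `baseline_memory_deterioration` flags.
#' @param family Outcome family string (from [outcome_registry()]).
#' @return A list: `data` (filtered tibble) and `n_excluded`.
#' @export
apply_exclusions <- function(data, family) {
  flag <- switch(family,
                 cognitive = "baseline_cognitive_dysfunction",
                 memory = "baseline_memory_deterioration",
                 NULL)
  if (is.null(flag)) return(list(data = data, n_excluded = 0L))
  if (!flag %in% names(data)) {
    abort(paste0("baseline flag '", flag, "' required for ", family,
                 " outcomes but missing"))
  }
  keep <- !data[[flag]]
  list(data = data[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Run the full association suite
#'
#' Fits the complete grid of exposures (machine-learning patterns and cut-off
#' symptom status) by outcomes and timepoints: logistic models for binary
#' outcomes, linear models for continuous outcomes standardized to 0-10
#' (length of stay on its raw day scale), the standard covariate adjustment
#' plus anesthesia type for discomfort outcomes, and baseline-condition
#' exclusions for the cognitive and memory families. Noise patients are
#' dropped with a logged count. Individual model failures are recorded as
#' rows with `NA` estimates and the error message; the suite continues.
#'
#' @param data Analysis tibble from [assemble_analysis_table()].
#' @param exposures Which exposures to fit.
#' @param subgroup Label stored in the `subgroup` column (`"all"` for the
#'   full cohort).
#' @param covariates Base adjustment set.
#' @return A long forest-plot tibble: `exposure_type`, `exposure_level`,
#'   `outcome`, `timepoint`, `subgroup`, `effect_type`, `estimate`, `ci_low`,
#'   `ci_high`, `p`, `n_used`, `n_excluded`, `n_noise`, `note`.
#' @export
run_association_suite <- function(data, exposures = c("pattern", "cutoff_status"),
                                  subgroup = "all",
                                  covariates = default_adjustment()) {
  reg <- outcome_registry()
  n_noise <- sum(is.na(data$pattern))
  data <- data[!is.na(data$pattern), , drop = FALSE] # noise excluded throughout
  rows <- list()
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    tps <- reg$timepoints[[i]]
    if (!length(tps)) tps <- NA_character_
    for (tp in tps) {
      col <- if (is.na(tp)) nm else paste(nm, tp, sep = "_")
      if (!col %in% names(data)) next
      adj <- covariates
      if (reg$family[i] == "discomfort") adj <- c(adj, "anesthesia_type")
      excl <- apply_exclusions(data, reg$family[i])
      d <- excl$data
      if (reg$type[i] == "continuous" && nm != "los_days") {
        d[[col]] <- standardize_0_10(d[[col]], reg$range_min[i], reg$range_max[i])
      }
      for (expo in exposures) {
        res <- tryCatch({
          f <- if (reg$type[i] == "binary") fit_binary else fit_linear
          f(d, col, expo, adj)
        }, error = function(e) {
          tibble(exposure_level = NA_character_,
                 effect_type = if (reg$type[i] == "binary") "OR" else "beta",
                 estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, n_used = 0L, n_excluded = NA_integer_,
                 note = conditionMessage(e))
        })
        rows[[length(rows) + 1]] <- mutate(
          res,
          exposure_type = expo, outcome = nm,
          timepoint = if (is.na(tp)) "" else tp,
          subgroup = subgroup,
          n_baseline_excluded = excl$n_excluded,
          n_noise = n_noise)
      }
    }
  }
  bind_rows(rows) |>
    select("exposure_type", "exposure_level", "outcome", "timepoint",
           "subgroup", "effect_type", "estimate", "ci_low", "ci_high", "p",
           "n_used", "n_excluded", "n_baseline_excluded", "n_noise", "note")
}

#' Association suite within surgery-site strata
#'
#' Refits the association suite separately within each surgery-site stratum
#' (surgery site dropped from the adjustment set, being constant within a
#' stratum). Strata too small to support a model are skipped with a warning.
#'
#' @param data Analysis tibble.
#' @param min_n Smallest stratum fitted.
#' @param ... Passed to [run_association_suite()].
#' @return The combined forest tibble with `subgroup` set to the site.
#' @export
subgroup_analyses <- function(data, min_n = 100, ...) {
  sites <- sort(unique(data$surgery_site))
  out <- list()
  for (site in sites) {
    d <- data[data$surgery_site == site, , drop = FALSE]
    if (nrow(d) < min_n) {
      warn(sprintf("surgery-site stratum '%s' has %d patients (< %d); skipped",
                   site, nrow(d), min_n))
      next
    }
    out[[site]] <- run_association_suite(
      d, subgroup = site,
      covariates = setdiff(default_adjustment(), "surgery_site"), ...)
  }
  bind_rows(out)
}
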