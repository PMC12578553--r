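#' Psychometric scale definitions
#'
#' The two preoperative screening instruments: the 9-item depression scale
#' (PHQ-9) and the 7-item anxiety scale (GAD-7). Each item is scored 0 ("not
#' at all") to 3 ("nearly every day"); both scales use a symptom-positive
#' cut-off of 10 on the total score.
#'
#' @param name `"PHQ9"` or `"GAD7"`.
#' @return A list with `name`, `n_items`, `items` (column names), `item_range`
#'   and `cutoff`.
#' @export
#' @examples
#' scale_definition("PHQ9")$cutoff
scale_definition <- function(name = c("PHQ9", "GAD7")) {
  name <- match.arg(name)
  if (name == "PHQ9") {
    list(name = "PHQ9", n_items = 9L, items = paste0("phq", 1:9),
         item_range = c(0L, 3L), cutoff = 10L)
  } else {
    list(name = "GAD7", n_items = 7L, items = paste0("gad", 1:7),
         item_range = c(0L, 3L), cutoff = 10L)
  }
}

#' Total score of one scale
#'
#' Sums the scale's items for each row. Missing or out-of-range items are an
#' error naming the offending column: cohorts with incomplete baseline
#' psychological assessments are excluded, not imputed.
#'
#' @param data Data frame containing the scale's item columns.
#' @param scale A [scale_definition()], or a scale name.
#' @return Integer vector of totals (0-27 for PHQ-9, 0-21 for GAD-7).
#' @export
#' @examples
#' score_scale(data.frame(t(setNames(rep(1, 9), paste0("phq", 1:9)))), "PHQ9")
score_scale <- function(data, scale) {
  if (is.character(scale)) scale <- scale_definition(scale)
  for (col in scale$items) {
    if (!col %in% names(data)) abort(paste0("missing item column: ", col))
    v <- data[[col]]
    if (anyNA(v)) abort(paste0("missing values in item: ", col))
    if (any(v < scale$item_range[1] | v > scale$item_range[2] | v != round(v))) {
      abort(paste0("out-of-range score in item: ", col))
    }
  }
  as.integer(rowSums(data[scale$items]))
}

#' Cut-off-based symptom classification
#'
#' A patient is symptom-positive when either total reaches the conventional
#' threshold: PHQ-9 total >= 10 or GAD-7 total >= 10 (both inclusive).
#'
#' @param phq_total,gad_total Integer totals within the scale ranges.
#' @return Logical vector.
#' @export
classify_cutoff <- function(phq_total, gad_total) {
  if (any(phq_total < 0 | phq_total > 27, na.rm = FALSE) || anyNA(phq_total)) {
    abort("phq_total must be within 0..27 and non-missing")
  }
  if (any(gad_total < 0 | gad_total > 21) || anyNA(gad_total)) {
    abort("gad_total must be within 0..21 and non-missing")
  }
  phq_total >= 10 | gad_total >= 10
}

#' Registry of surgery-related outcomes
#'
#' One row per outcome: its type, native score range, assessment timepoints,
#' adverse direction, outcome family (used for baseline-condition exclusions
#' and the anesthesia-type extra adjustment) and, for binary outcomes derived
#' from a raw score, the threshold rule.
#'
#' Binary rules as published: sleep disturbance is PSQI total > 5 (exclusive);
#' memory deterioration is failure to recall all three words (< 3 recalled);
#' cognitive dysfunction is AD8 total < 2 — the printed rule, which inverts
#' the usual AD8 direction (see `ad8_low_is_impaired` in [classify_outcome()]).
#' Complication flags are consumed as already-adjudicated binaries.
#'
#' @return A tibble.
#' @export
outcome_registry <- function() {
  tibble(
    name = c("los_days", "any_complication", "pulmonary_complication",
             "infection", "pain_rest", "pain_move", "nausea",
             "cognitive_dysfunction", "memory_deterioration",
             "sleep_disturbance", "recovery", "life_satisfaction"),
    type = c("continuous", "binary", "binary", "binary", "continuous",
             "continuous", "continuous", "binary", "binary", "binary",
             "continuous", "continuous"),
    range_min = c(0, NA, NA, NA, 0, 0, 0, NA, NA, NA, 0, 0),
    range_max = c(NA, NA, NA, NA, 10, 10, 10, NA, NA, NA, 10, 4),
    timepoints = list(character(0), character(0), character(0), character(0),
                      c("d1", "d3"), c("d1", "d3"), c("d1", "d3"),
                      c("m1", "m6", "m12"), c("m1", "m6", "m12"),
                      c("m1", "m6", "m12"), c("m1", "m6", "m12"),
                      c("m1", "m6", "m12")),
    family = c("hospital", "complication", "complication", "complication",
               "discomfort", "discomfort", "discomfort",
               "cognitive", "memory", "sleep", "recovery", "satisfaction"),
    adverse_high = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                     TRUE, FALSE, FALSE)
  )
}

#' Classify a raw instrument score into a binary outcome
#'
#' Applies the published threshold rules: PSQI > 5 is sleep disturbance,
#' recalling fewer than all three words is memory deterioration, and AD8 < 2
#' is cognitive dysfunction. The AD8 rule is implemented exactly as printed;
#' because it runs opposite to the instrument's usual direction (AD8 >= 2
#' impaired), the flag `ad8_low_is_impaired` makes the choice explicit and
#' reversible without silently correcting the published definition.
#'
#' @param raw Numeric vector of raw scores.
#' @param outcome One of `"sleep_disturbance"` (PSQI, 0-21),
#'   `"memory_deterioration"` (words recalled, 0-3), or
#'   `"cognitive_dysfunction"` (AD8, 0-8).
#' @param ad8_low_is_impaired Apply the printed AD8 < 2 rule (default); set
#'   `FALSE` for the conventional AD8 >= 2 rule.
#' @return Logical vector, `TRUE` = adverse.
#' @export
#' @examples
#' classify_outcome(6, "sleep_disturbance") # PSQI 6 -> disturbed
#' classify_outcome(3, "memory_deterioration") # all three words -> FALSE
classify_outcome <- function(raw, outcome, ad8_low_is_impaired = TRUE) {
  switch(outcome,
    sleep_disturbance = {
      if (any(raw < 0 | raw > 21)) abort("PSQI total must be within 0..21")
      raw > 5
    },
    memory_deterioration = {
      if (any(raw < 0 | raw > 3)) abort("words recalled must be within 0..3")
      raw < 3
    },
    cognitive_dysfunction = {
      if (any(raw < 0 | raw > 8)) abort("AD8 total must be within 0..8")
      if (ad8_low_is_impaired) raw < 2 else raw >= 2
    },
    abort(paste0("unknown outcome: ", outcome))
  )
}

#' Standardize scores to a 0-10 scale
#'
#' Affine map from a native range onto 0-10, as used before fitting linear
#' models so that slopes are comparable across instruments.
#'
#' @param values Numeric vector.
#' @param range_min,range_max Native range endpoints (`range_max > range_min`).
#' @return Numeric vector on 0-10.
#' @export
#' @examples
#' standardize_0_10(2, 0, 4) # midpoint -> 5
standardize_0_10 <- function(values, range_min, range_max) {
  if (!is.finite(range_min) || !is.finite(range_max) || range_max <= range_min) {
    abort("degenerate native range")
  }
  if (any(values < range_min | values > range_max, na.rm = TRUE)) {
    abort("values outside the native range")
  }
  10 * (values - range_min) / (range_max - range_min)
}
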