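# Seven-metric CVH classification (modified AHA construct for children).
#
# Each metric is graded poor / intermediate / ideal; smoking has no
# intermediate level.  The composite CVH score counts metrics at the ideal
# level (0-7) and splits into a behavior score (smoking, BMI, physical
# activity, diet; 0-4) and a factor score (blood pressure, total
# cholesterol, fasting glucose; 0-3).
#
# Boundary semantics (documented defaults):
#   BMI:   ideal < p85; intermediate p85 <= bmi <= p95; poor > p95.
#   BP:    poor if SBP > p95 or DBP > p95; else intermediate if SBP >= p90
#          or DBP >= p90 or SBP >= 120 or DBP >= 80 mmHg; else ideal.
#   TC:    ideal < 170; intermediate [170, 200); poor >= 200 mg/dL.
#   FBG:   ideal < 100; intermediate [100, 126); poor >= 126 mg/dL.
#   MVPA:  poor = 0 min/d; intermediate (0, 60); ideal >= 60.
#   Diet:  5 components; ideal 4-5, intermediate 2-3, poor 0-1.
# The lab bands are half-open real intervals so every positive value maps to
# exactly one status.

#' Body-mass index
#'
#' @param weight weight in kg.
#' @param height height in cm.
#' @return BMI in kg/m2.
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.na(weight) & weight <= 0) || any(!is.na(height) & height <= 0)) {
    stop_pedcvh("compute_bmi: weight and height must be positive")
  }
  weight / (height / 100)^2
}

#' @rdname classify_metric
#' @export
classify_smoking <- function(smoked_past_30d) {
  status_factor(ifelse(is.na(smoked_past_30d), NA_character_,
                       ifelse(smoked_past_30d, "poor", "ideal")))
}

#' @rdname classify_metric
#' @export
classify_bmi <- function(bmi, p85, p95) {
  status_factor(ifelse(is.na(bmi), NA_character_,
                ifelse(bmi > p95, "poor",
                ifelse(bmi >= p85, "intermediate", "ideal"))))
}

#' @rdname classify_metric
#' @export
classify_physical_activity <- function(mvpa_minutes_per_day) {
  if (any(mvpa_minutes_per_day < 0, na.rm = TRUE)) {
    stop_pedcvh("MVPA minutes cannot be negative")
  }
  status_factor(ifelse(is.na(mvpa_minutes_per_day), NA_character_,
                ifelse(mvpa_minutes_per_day >= 60, "ideal",
                ifelse(mvpa_minutes_per_day > 0, "intermediate", "poor"))))
}

#' Count satisfied healthy-diet components
#'
#' The five components: fruits and vegetables >= 1/day; aquatic foods
#' >= 1/week; fried or western fast food <= 1/week (inclusive); sugar-
#' sweetened beverages < 1/week (strict); bean-curd or dairy >= 1/day.
#'
#' @param fruit_veg,bean_dairy times per day.
#' @param aquatic,fried_fast,ssb times per week.
#' @return integer count 0-5 (NA if any component frequency is missing).
#' @export
score_diet_components <- function(fruit_veg, aquatic, fried_fast, ssb, bean_dairy) {
  cnt <- (fruit_veg >= 1) + (aquatic >= 1) + (fried_fast <= 1) +
    (ssb < 1) + (bean_dairy >= 1)
  as.integer(cnt)
}

#' @rdname classify_metric
#' @export
classify_diet <- function(count) {
  if (any(count < 0 | count > 5, na.rm = TRUE)) {
    stop_pedcvh("diet component count must be in 0..5")
  }
  status_factor(ifelse(is.na(count), NA_character_,
                ifelse(count >= 4, "ideal",
                ifelse(count >= 2, "intermediate", "poor"))))
}

#' @rdname classify_metric
#' @export
classify_tc <- function(tc) {
  if (any(tc <= 0, na.rm = TRUE)) stop_pedcvh("total cholesterol must be positive")
  status_factor(ifelse(is.na(tc), NA_character_,
                ifelse(tc >= 200, "poor",
                ifelse(tc >= 170, "intermediate", "ideal"))))
}

#' @rdname classify_metric
#' @export
classify_fbg <- function(fbg) {
  if (any(fbg <= 0, na.rm = TRUE)) stop_pedcvh("fasting glucose must be positive")
  status_factor(ifelse(is.na(fbg), NA_character_,
                ifelse(fbg >= 126, "poor",
                ifelse(fbg >= 100, "intermediate", "ideal"))))
}

#' Classify individual CVH metrics
#'
#' Vectorized poor/intermediate/ideal grading of single metrics.  Missing
#' inputs yield NA statuses (the record is then invalid for composite
#' scoring, mirroring a valid-CVH-metrics inclusion rule).
#'
#' @param smoked_past_30d logical; tried smoking in the prior 30 days.
#' @param bmi BMI in kg/m2; `p85`, `p95` the reference cut-offs.
#' @param mvpa_minutes_per_day daily moderate-to-vigorous activity minutes.
#' @param count satisfied diet components (0-5).
#' @param tc total cholesterol, mg/dL.
#' @param fbg fasting glucose, mg/dL.
#' @param sbp,dbp averaged systolic/diastolic pressure, mmHg.
#' @param cutoffs data frame from [bp_cutoffs()].
#' @return ordered status factor.
#' @name classify_metric
NULL

#' @rdname classify_metric
#' @export
classify_bp <- function(sbp, dbp, cutoffs) {
  poor <- sbp > cutoffs$sbp_p95 | dbp > cutoffs$dbp_p95
  inter <- sbp >= cutoffs$sbp_p90 | dbp >= cutoffs$dbp_p90 |
    sbp >= 120 | dbp >= 80
  status_factor(ifelse(is.na(sbp) | is.na(dbp), NA_character_,
                ifelse(poor, "poor", ifelse(inter, "intermediate", "ideal"))))
}

#' CVH profiles for a participant table
#'
#' Classifies all seven metrics for each record and assembles the composite
#' scores: `cvh_score` = number of ideal metrics (0-7), `behavior_score`
#' (0-4, smoking/BMI/activity/diet), `factor_score` (0-3, BP/TC/FBG);
#' `cvh_category` ideal for scores 6-7, intermediate 3-5, poor 0-2;
#' `ideal_behaviors` for behavior score 3-4, `ideal_factors` for factor
#' score 3.  Records with any unclassifiable metric get `valid = FALSE` and
#' NA scores rather than an error.
#'
#' @param data participant data frame (see [participant_columns()]).
#' @param refs a [reference_set()].
#' @return data frame of per-metric statuses, scores, categories and flags,
#'   one row per input record.
#' @export
cvh_profile <- function(data, refs) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  bmi <- compute_bmi(data$weight, data$height)
  bcut <- bmi_cutoffs(refs, data$sex, data$age)
  pcut <- bp_cutoffs(refs, data$sex, data$age, data$height)
  diet_n <- score_diet_components(data$diet_fruit_veg, data$diet_aquatic,
                                  data$diet_fried_fast, data$diet_ssb,
                                  data$diet_bean_dairy)
  st <- data.frame(
    id = data$id,
    survey_year = data$survey_year,
    smoking = classify_smoking(data$smoked_past_30d),
    bmi = classify_bmi(bmi, bcut$p85, bcut$p95),
    physical_activity = classify_physical_activity(data$mvpa_minutes_per_day),
    diet = classify_diet(diet_n),
    bp = classify_bp(data$sbp, data$dbp, pcut),
    tc = classify_tc(data$tc),
    fbg = classify_fbg(data$fbg)
  )
  st$diet_component_count <- diet_n
  beh <- c("smoking", "bmi", "physical_activity", "diet")
  fac <- c("bp", "tc", "fbg")
  ideal_mat <- sapply(st[c(beh, fac)], function(s) s == "ideal")
  if (n == 1L) ideal_mat <- matrix(ideal_mat, nrow = 1,
                                   dimnames = list(NULL, c(beh, fac)))
  st$valid <- !apply(is.na(ideal_mat), 1L, any)
  st$behavior_score <- ifelse(st$valid,
                              rowSums(ideal_mat[, beh, drop = FALSE]), NA)
  st$factor_score <- ifelse(st$valid,
                            rowSums(ideal_mat[, fac, drop = FALSE]), NA)
  st$cvh_score <- st$behavior_score + st$factor_score
  st$cvh_category <- status_factor(
    ifelse(!st$valid, NA_character_,
    ifelse(st$cvh_score >= 6, "ideal",
    ifelse(st$cvh_score >= 3, "intermediate", "poor"))))
  st$ideal_behaviors <- st$behavior_score >= 3
  st$ideal_factors <- st$factor_score == 3
  st
}

#' Missing-metric exclusion reasons
#'
#' @param data participant data frame.
#' @param refs a [reference_set()].
#' @return character vector, "" for scorable records, otherwise a
#'   comma-separated list like "metric-missing:tc".
#' @export
metric_missing_reasons <- function(data, refs) {
  prof <- cvh_profile(data, refs)
  metrics <- c("smoking", "bmi", "physical_activity", "diet", "bp", "tc", "fbg")
  apply(prof[metrics], 1L, function(r) {
    miss <- metrics[is.na(r)]
    if (!length(miss)) "" else paste0("metric-missing:", miss, collapse = ",")
  })
}
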