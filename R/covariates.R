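# Questionnaire-derived covariates used in the association models.

#' Participant column dictionary
#'
#' Names and meanings of the columns expected in a participant table.  One
#' row per child per survey wave; missing values are NA (empty cells in
#' CSV).  Units: height cm, weight and fat mass kg, BP mmHg, TC and FBG
#' mg/dL (use [to_mgdl()] for mmol/L sources), activity minutes/day,
#' sedentary and sleep hours/day, diet frequencies per day or per week as
#' indicated by the column name.
#'
#' @return data frame with columns `column`, `type`, `description`.
#' @export
participant_columns <- function() {
  d <- function(column, type, description) data.frame(column, type, description)
  rbind(
    d("id", "character", "participant identifier"),
    d("survey_year", "integer", "survey wave (e.g. 2004/2014/2019)"),
    d("sex", "factor", "male/female"),
    d("age", "numeric", "age in years, 6-18"),
    d("height", "numeric", "height, cm"),
    d("weight", "numeric", "weight, kg"),
    d("fat_mass", "numeric", "body fat mass, kg (optional)"),
    d("sbp", "numeric", "systolic BP, mmHg (average of last two readings)"),
    d("dbp", "numeric", "diastolic BP, mmHg (average of last two readings)"),
    d("tc", "numeric", "total cholesterol, mg/dL"),
    d("fbg", "numeric", "fasting glucose, mg/dL"),
    d("smoked_past_30d", "logical", "tried smoking in the past 30 days"),
    d("mvpa_minutes_per_day", "numeric", "moderate-to-vigorous activity, min/d"),
    d("diet_fruit_veg", "numeric", "fruit & vegetable intake, times/day"),
    d("diet_aquatic", "numeric", "aquatic foods, times/week"),
    d("diet_fried_fast", "numeric", "fried/western fast food, times/week"),
    d("diet_ssb", "numeric", "sugar-sweetened beverages, times/week"),
    d("diet_bean_dairy", "numeric", "bean-curd or dairy, times/day"),
    d("sedentary_hours_per_day", "numeric", "sedentary time, h/d"),
    d("sleep_hours_per_day", "numeric", "sleep duration, h/d"),
    d("smoke_env_days_per_week", "numeric", "days/week in a smoking environment"),
    d("parent_current_smoker", "logical", "either parent currently smokes"),
    d("household_income", "factor", "poor/middle/high"),
    d("paternal_education", "factor", "below_college/college_plus"),
    d("maternal_education", "factor", "below_college/college_plus"),
    d("paternal_bmi", "numeric", "father's BMI, kg/m2"),
    d("maternal_bmi", "numeric", "mother's BMI, kg/m2"),
    d("parental_cvd_history", "logical", "parental coronary disease or stroke"),
    d("premature", "logical", "born before 37 completed weeks"),
    d("sexually_mature", "logical", "spermatorrhea/menstruation occurred")
  )
}

#' Parental weight status from BMI
#'
#' Adult bands: normal < 24, overweight 24 to < 28, obesity >= 28 kg/m2.
#'
#' @param bmi parental BMI, kg/m2.
#' @return factor normal/overweight/obesity.
#' @export
parental_weight_status <- function(bmi) {
  factor(ifelse(is.na(bmi), NA_character_,
         ifelse(bmi >= 28, "obesity",
         ifelse(bmi >= 24, "overweight", "normal"))),
         levels = c("normal", "overweight", "obesity"))
}

#' Age-appropriate sleep adequacy
#'
#' Adequate sleep is 9-12 h/day for ages 6-12 and 8-10 h/day for ages
#' 13-18 (completed years; age 12 uses the younger band).
#'
#' @param age age in years.
#' @param sleep_hours sleep duration, h/day.
#' @return logical.
#' @export
sleep_adequate <- function(age, sleep_hours) {
  young <- floor(age) <= 12
  ifelse(young, sleep_hours >= 9 & sleep_hours <= 12,
         sleep_hours >= 8 & sleep_hours <= 10)
}

#' Derive analysis covariates from raw fields
#'
#' Adds the derived variables the association models adjust for:
#' \itemize{
#'   \item `bmi`, and `fmp` = 100 * fat mass / weight (percent);
#'   \item `fmp_tertile` (T1/T2/T3), computed within survey year because
#'     body-composition devices differ across waves;
#'   \item `passive_smoking`: in a smoking environment more than 1 day/week
#'     (> 1, i.e. >= 2 for integer answers) or a currently smoking parent;
#'   \item `sedentary_flag`: sedentary time >= 2 h/day;
#'   \item `sleep_adequate_flag` per the age-specific bands;
#'   \item `paternal_weight_status` / `maternal_weight_status`;
#'   \item `age_group`: 6-11 vs 12-18 completed years.
#' }
#' Missingness propagates as NA; multiple imputation handles it downstream.
#'
#' @param data participant data frame.
#' @return `data` with the derived columns appended.
#' @export
derive_covariates <- function(data) {
  data$bmi <- compute_bmi(data$weight, data$height)
  data$fmp <- ifelse(is.na(data$fat_mass), NA_real_,
                     100 * data$fat_mass / data$weight)
  data$fmp_tertile <- factor(NA_character_, levels = c("T1", "T2", "T3"))
  for (yr in unique(data$survey_year)) {
    i <- which(data$survey_year == yr & !is.na(data$fmp))
    if (length(i) >= 3) {
      qs <- stats::quantile(data$fmp[i], c(1, 2) / 3, names = FALSE)
      breaks <- unique(c(-Inf, qs, Inf))   # ties collapse degenerate bands
      data$fmp_tertile[i] <- cut(data$fmp[i], breaks,
                                 labels = c("T1", "T2", "T3")[seq_len(length(breaks) - 1)])
    }
  }
  # R's three-valued OR: a TRUE on either side dominates a missing other side
  data$passive_smoking <- (data$smoke_env_days_per_week > 1) |
    data$parent_current_smoker
  data$sedentary_flag <- data$sedentary_hours_per_day >= 2
  data$sleep_adequate_flag <- sleep_adequate(data$age, data$sleep_hours_per_day)
  data$paternal_weight_status <- parental_weight_status(data$paternal_bmi)
  data$maternal_weight_status <- parental_weight_status(data$maternal_bmi)
  data$age_group <- factor(ifelse(floor(data$age) <= 11, "6-11", "12-18"),
                           levels = c("6-11", "12-18"))
  data
}
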