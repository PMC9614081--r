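# Pipeline driver: simulate -> score -> report -> associate, with CSV
# outputs shaped like survey-trend publication tables and a manifest that
# records seeds and configuration hashes for reproducibility.

manifest_add <- function(outdir, entry) {
  path <- file.path(outdir, "manifest.json")
  man <- if (file.exists(path)) jsonlite::read_json(path) else list()
  man[[length(man) + 1L]] <- entry
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

spec_hash <- function(x) {
  # stable content hash without extra dependencies
  s <- paste(utils::capture.output(utils::str(x, digits.d = 12)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% .Machine$integer.max)
}

write_csv0 <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE, na = "")
  path
}

#' Simulate a multi-wave cohort to CSV
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param presets list of [cohort_spec()]s (default [wave_presets()]).
#' @param n_per_wave optional common per-wave n override.
#' @return invisibly, list with file paths and the generated cohorts.
#' @export
run_simulate <- function(outdir, seed = 1, presets = wave_presets(),
                         n_per_wave = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gw <- generate_waves(presets, seed = seed, n_per_wave = n_per_wave)
  truth <- do.call(rbind, lapply(gw$cohorts, `[[`, "truth"))
  p_path <- write_csv0(gw$participants, file.path(outdir, "participants.csv"))
  t_path <- write_csv0(truth, file.path(outdir, "ground_truth.csv"))
  manifest_add(outdir, list(stage = "simulate", seed = seed,
                            spec_hash = spec_hash(presets),
                            n = nrow(gw$participants),
                            files = c("participants.csv", "ground_truth.csv")))
  message(sprintf("simulate: %d records across %d waves",
                  nrow(gw$participants), length(presets)))
  invisible(list(participants = p_path, truth = t_path, cohorts = gw$cohorts,
                 data = gw$participants))
}

#' Score a participant table and log exclusions
#'
#' Computes CVH profiles for metric-complete records; excluded records are
#' logged with per-metric reasons, mirroring a valid-CVH-metrics inclusion
#' rule.
#'
#' @param data participant data frame (or path to the CSV).
#' @param outdir output directory.
#' @param refs a [reference_set()].
#' @return invisibly, list with `profiles` (data frame, scorable records),
#'   `exclusions`, file paths.
#' @export
run_score <- function(data, outdir, refs = synthetic_reference_set()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(data)) data <- utils::read.csv(data, stringsAsFactors = FALSE)
  prof <- cvh_profile(data, refs)
  reasons <- metric_missing_reasons(data, refs)
  excl <- data.frame(id = data$id, reason = reasons)[reasons != "", ]
  keep <- prof$valid
  p_path <- write_csv0(prof[keep, ], file.path(outdir, "profiles.csv"))
  e_path <- write_csv0(excl, file.path(outdir, "exclusions.csv"))
  manifest_add(outdir, list(stage = "score", records_in = nrow(data),
                            records_scored = sum(keep),
                            records_excluded = sum(!keep),
                            files = c("profiles.csv", "exclusions.csv")))
  message(sprintf("score: %d in, %d scored, %d excluded",
                  nrow(data), sum(keep), sum(!keep)))
  invisible(list(profiles = prof[keep, ], exclusions = excl,
                 paths = c(p_path, e_path)))
}

fmt_prev <- function(k, n) {
  ci <- prevalence_ci(k, n)
  sprintf("%.1f (%.1f-%.1f)", 100 * ci$proportion, 100 * ci$lower, 100 * ci$upper)
}

report_scores_panel <- function(prof, label) {
  waves <- sort(unique(prof$survey_year))
  rows <- lapply(waves, function(w) {
    p <- prof[prof$survey_year == w, ]
    data.frame(
      population = label, year = w, n = nrow(p),
      cvh_score = sprintf("%.2f (%.2f)", mean(p$cvh_score), stats::sd(p$cvh_score)),
      behavior_score = sprintf("%.2f (%.2f)", mean(p$behavior_score),
                               stats::sd(p$behavior_score)),
      factor_score = sprintf("%.2f (%.2f)", mean(p$factor_score),
                             stats::sd(p$factor_score)),
      ideal_cvh = fmt_prev(sum(p$cvh_category == "ideal"), nrow(p)),
      ideal_behaviors = fmt_prev(sum(p$ideal_behaviors), nrow(p)),
      ideal_factors = fmt_prev(sum(p$ideal_factors), nrow(p))
    )
  })
  out <- do.call(rbind, rows)
  if (length(waves) >= 2) {
    out$p_trend_ideal_cvh <- c(
      trend_test(prof$cvh_category == "ideal", prof$survey_year)$p.value,
      rep(NA, length(waves) - 1))
  } else {
    out$p_trend_ideal_cvh <- NA_real_
  }
  out
}

metric_status_panel <- function(prof, metric) {
  waves <- sort(unique(prof$survey_year))
  levs <- c("poor", "intermediate", "ideal")
  if (metric == "smoking") levs <- c("poor", "ideal")
  rows <- list()
  for (lv in levs) {
    cells <- vapply(waves, function(w) {
      s <- prof[[metric]][prof$survey_year == w]
      fmt_prev(sum(s == lv), length(s))
    }, character(1))
    rows[[lv]] <- data.frame(metric = metric, status = lv,
                             t(stats::setNames(cells, paste0("y", waves))),
                             check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_trend <- NA_real_
  if (length(waves) >= 2) {
    out$p_trend[1] <- trend_test(prof[[metric]] == "ideal",
                                 prof$survey_year)$p.value
  }
  rownames(out) <- NULL
  out
}

#' Publication-shaped trend report
#'
#' Writes score/prevalence panels (overall and by sex and age group), a
#' per-metric status-proportion table with trend p-values, a CVH score
#' distribution table and a diet-component count table.
#'
#' @param profiles scored profile data frame from [run_score()].
#' @param data participant data frame (for sex/age stratification).
#' @param outdir output directory.
#' @return invisibly, list of the written data frames.
#' @export
run_report <- function(profiles, data, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data <- derive_covariates(data)
  idx <- match(profiles$id, data$id)
  profiles$sex <- data$sex[idx]
  profiles$age_group <- data$age_group[idx]

  panels <- rbind(
    report_scores_panel(profiles, "overall"),
    report_scores_panel(profiles[profiles$sex == "male", ], "boys"),
    report_scores_panel(profiles[profiles$sex == "female", ], "girls"),
    report_scores_panel(profiles[profiles$age_group == "6-11", ], "6-11y"),
    report_scores_panel(profiles[profiles$age_group == "12-18", ], "12-18y"))
  metrics <- c("smoking", "bmi", "physical_activity", "diet", "bp", "tc", "fbg")
  status_tab <- do.call(rbind, lapply(metrics, metric_status_panel,
                                      prof = profiles))
  score_dist <- as.data.frame(
    prop.table(table(score = profiles$cvh_score,
                     year = profiles$survey_year), 2) * 100)
  diet_dist <- as.data.frame(
    prop.table(table(components = profiles$diet_component_count,
                     year = profiles$survey_year), 2) * 100)

  write_csv0(panels, file.path(outdir, "table_scores.csv"))
  write_csv0(status_tab, file.path(outdir, "table_metric_status.csv"))
  write_csv0(score_dist, file.path(outdir, "score_distribution.csv"))
  write_csv0(diet_dist, file.path(outdir, "diet_components.csv"))
  manifest_add(outdir, list(stage = "report",
                            files = c("table_scores.csv",
                                      "table_metric_status.csv",
                                      "score_distribution.csv",
                                      "diet_components.csv")))
  invisible(list(scores = panels, status = status_tab,
                 score_distribution = score_dist, diet = diet_dist))
}

#' Default association model formula
#'
#' Ideal CVH regressed on the demographic factors the analysis adjusts
#' for: sex, age group, household income, parental education and weight
#' status, parental CVD history, passive smoking, sedentary time, sleep
#' adequacy, prematurity, sexual maturity, fat-mass tertile and survey
#' year.
#'
#' @return a formula.
#' @export
default_association_formula <- function() {
  ideal_cvh ~ sex + age_group + household_income + paternal_education +
    maternal_education + paternal_weight_status + maternal_weight_status +
    parental_cvd_history + passive_smoking + sedentary_flag +
    sleep_adequate_flag + premature + sexually_mature + fmp_tertile +
    survey_wave
}

#' Assemble the modeling frame for the association stage
#'
#' @param profiles scored profiles.
#' @param data participant data frame.
#' @return data frame with the outcome `ideal_cvh`, derived covariates and
#'   `survey_wave` factor.
#' @export
association_frame <- function(profiles, data) {
  data <- derive_covariates(data)
  idx <- match(profiles$id, data$id)
  out <- data.frame(
    ideal_cvh = profiles$cvh_category == "ideal",
    sex = factor(data$sex[idx], levels = SEX_LEVELS),
    age_group = data$age_group[idx],
    household_income = data$household_income[idx],
    paternal_education = data$paternal_education[idx],
    maternal_education = data$maternal_education[idx],
    paternal_weight_status = data$paternal_weight_status[idx],
    maternal_weight_status = data$maternal_weight_status[idx],
    parental_cvd_history = data$parental_cvd_history[idx],
    passive_smoking = data$passive_smoking[idx],
    sedentary_flag = data$sedentary_flag[idx],
    sleep_adequate_flag = data$sleep_adequate_flag[idx],
    premature = data$premature[idx],
    sexually_mature = data$sexually_mature[idx],
    fmp_tertile = data$fmp_tertile[idx],
    survey_wave = factor(profiles$survey_year)
  )
  out
}

#' Pooled association and PAR analysis
#'
#' Runs chained-equation imputation on the association frame, fits the
#' logistic model per imputation, pools odds ratios with Rubin's rules and
#' adds a complete-case sensitivity fit.  Also computes the PAR of
#' overweight/obesity (BMI status not ideal) for each CVH factor (poor BP,
#' poor TC, poor FBG) per wave by model standardization.
#'
#' @param profiles scored profiles from [run_score()].
#' @param data participant data frame.
#' @param outdir output directory.
#' @param m,maxit imputation settings (defaults 30 and 10).
#' @param seed seed for imputation and bootstraps.
#' @param formula association model (default
#'   [default_association_formula()]).
#' @param par_boot bootstrap resamples for each PAR CI.
#' @return invisibly, list with `pooled` (MI OR table), `complete_case`,
#'   `par_table`.
#' @export
run_associate <- function(profiles, data, outdir, m = 30, maxit = 10,
                          seed = 1, formula = default_association_formula(),
                          par_boot = 200) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  frame <- association_frame(profiles, data)
  vars <- all.vars(formula)

  mi <- impute_chained(frame[vars], m = m, maxit = maxit, seed = seed)
  pooled <- run_association_suite(mi$imputations, formula)
  cc <- frame[stats::complete.cases(frame[vars]), ]
  cc_fit <- fit_logistic(formula, cc)

  write_csv0(pooled$or_table, file.path(outdir, "or_pooled_mi.csv"))
  write_csv0(cc_fit$table, file.path(outdir, "or_complete_case.csv"))

  par_tab <- par_table(profiles, data, boot = par_boot, seed = seed)
  write_csv0(par_tab, file.path(outdir, "par_overweight.csv"))

  manifest_add(outdir, list(stage = "associate", mi_m = m, mi_maxit = maxit,
                            seed = seed, model_hash = spec_hash(deparse(formula)),
                            files = c("or_pooled_mi.csv", "or_complete_case.csv",
                                      "par_overweight.csv")))
  invisible(list(pooled = pooled, complete_case = cc_fit, par_table = par_tab,
                 mi = mi))
}

#' PAR of overweight/obesity for each CVH factor
#'
#' For each survey wave and each CVH factor outcome (poor blood pressure,
#' poor total cholesterol, poor fasting glucose), estimates the
#' model-standardized attributable fraction of overweight/obesity (BMI
#' status not ideal), adjusted for sex and age group, with stratified
#' (overall / boys / girls) panels.
#'
#' @param profiles scored profiles.
#' @param data participant data frame.
#' @param factors named list mapping output labels to profile status
#'   columns (default BP/TC/FBG).
#' @param boot bootstrap resamples per cell.
#' @param seed seed.
#' @return data frame: factor, stratum, year, af (%), lower, upper.
#' @export
par_table <- function(profiles, data,
                      factors = c(poor_bp = "bp", poor_tc = "tc",
                                  poor_fbg = "fbg"),
                      boot = 200, seed = 1) {
  data <- derive_covariates(data)
  idx <- match(profiles$id, data$id)
  base <- data.frame(
    overweight = profiles$bmi != "ideal",
    sex = factor(data$sex[idx], levels = SEX_LEVELS),
    age_group = data$age_group[idx],
    year = profiles$survey_year
  )
  rows <- list()
  for (f in names(factors)) {
    base$outcome <- profiles[[factors[[f]]]] == "poor"
    for (stratum in c("overall", "boys", "girls")) {
      sel <- switch(stratum, overall = rep(TRUE, nrow(base)),
                    boys = base$sex == "male", girls = base$sex == "female")
      for (yr in sort(unique(base$year))) {
        d <- base[sel & base$year == yr, ]
        form <- if (stratum == "overall") {
          outcome ~ overweight + sex + age_group
        } else {
          outcome ~ overweight + age_group
        }
        res <- tryCatch(
          par_standardized(form, d, "overweight", boot = boot, seed = seed),
          error = function(e) list(af = NA_real_, lower = NA_real_,
                                   upper = NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          factor = f, stratum = stratum, year = yr,
          af_pct = 100 * res$af, lower_pct = 100 * res$lower,
          upper_pct = 100 * res$upper)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' simulate -> score -> report -> associate under one master seed; all
#' stages write into `outdir` and append to its manifest.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @param n_per_wave optional per-wave n override (smaller = faster).
#' @param m,maxit imputation settings.
#' @param par_boot bootstrap resamples per PAR cell.
#' @return invisibly, list of stage results.
#' @export
run_pipeline <- function(outdir, seed = 1, n_per_wave = NULL, m = 30,
                         maxit = 10, par_boot = 200) {
  sim <- run_simulate(outdir, seed = seed, n_per_wave = n_per_wave)
  sc <- run_score(sim$data, outdir)
  rep <- run_report(sc$profiles, sim$data, outdir)
  as <- run_associate(sc$profiles, sim$data, outdir, m = m, maxit = maxit,
                      seed = seed, par_boot = par_boot)
  invisible(list(simulate = sim, score = sc, report = rep, associate = as))
}
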