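test_that("BMI formula and input validation", {
  expect_equal(compute_bmi(50, 160), 50 / 1.6^2)
  expect_equal(compute_bmi(1, 100), 1)
  expect_error(compute_bmi(0, 160), "positive")
})

test_that("single-metric thresholds classify per the construct", {
  expect_equal(as.character(classify_smoking(c(TRUE, FALSE, NA))),
               c("poor", "ideal", NA))
  # smoking admits no intermediate level
  expect_false("intermediate" %in% classify_smoking(c(TRUE, FALSE)))

  expect_equal(as.character(classify_bmi(c(17, 20, 20.01, 23, 23.1), 20, 23)),
               c("ideal", "intermediate", "intermediate", "intermediate", "poor"))

  expect_equal(as.character(classify_physical_activity(c(0, 1, 30, 59.9, 60, 75))),
               c("poor", "intermediate", "intermediate", "intermediate",
                 "ideal", "ideal"))
  expect_error(classify_physical_activity(-5), "negative")

  expect_equal(as.character(classify_tc(c(150, 169.99, 170, 185, 199.5, 200, 240))),
               c("ideal", "ideal", "intermediate", "intermediate",
                 "intermediate", "poor", "poor"))
  expect_equal(as.character(classify_fbg(c(99, 99.9, 100, 125, 125.5, 126, 180))),
               c("ideal", "ideal", "intermediate", "intermediate",
                 "intermediate", "poor", "poor"))
  expect_error(classify_tc(0), "positive")
  expect_error(classify_fbg(-2), "positive")
})

test_that("lab bands are gapless over positive reals", {
  x <- c(seq(0.5, 400, by = 0.37), 99.999, 100, 125.999, 126,
         169.999, 170, 199.999, 200)
  expect_false(anyNA(classify_tc(x)))
  expect_false(anyNA(classify_fbg(x)))
})

test_that("diet component counting honors inclusive/strict limits", {
  # all components exactly at their satisfying limits; fried <= 1 inclusive
  expect_equal(score_diet_components(1, 1, 1, 0, 1), 5L)
  # ssb at exactly 1/week fails the strict < 1 rule
  expect_equal(score_diet_components(1, 1, 1, 1, 1), 4L)
  expect_equal(score_diet_components(0, 0, 2, 2, 0), 0L)
  expect_true(is.na(score_diet_components(1, NA, 1, 0, 1)))
  expect_equal(as.character(classify_diet(c(0, 1, 2, 3, 4, 5))),
               c("poor", "poor", "intermediate", "intermediate",
                 "ideal", "ideal"))
  expect_error(classify_diet(6), "0..5")
})

test_that("BP rule: percentile bands, absolute 120/80 rule, worse-of-two", {
  cuts <- data.frame(sbp_p90 = 110, sbp_p95 = 115, dbp_p90 = 72, dbp_p95 = 76)
  expect_equal(as.character(classify_bp(105, 65, cuts)), "ideal")
  # poor via SBP above p95 even with ideal DBP
  expect_equal(as.character(classify_bp(116, 65, cuts)), "poor")
  # intermediate via DBP at p90 with ideal SBP
  expect_equal(as.character(classify_bp(105, 72, cuts)), "intermediate")
  # absolute SBP >= 120 rule fires below the percentile cut
  cuts2 <- data.frame(sbp_p90 = 122, sbp_p95 = 126, dbp_p90 = 80, dbp_p95 = 84)
  expect_equal(as.character(classify_bp(121, 65, cuts2)), "intermediate")
  expect_equal(as.character(classify_bp(105, 79.5, cuts2)), "ideal")
  expect_equal(as.character(classify_bp(105, 80, cuts2)), "intermediate")
  expect_true(is.na(classify_bp(NA, 70, cuts)))
})

test_that("exhaustive boundary sweep at the percentile cut-offs", {
  rec <- ideal_record()
  cut <- bmi_cutoffs(REFS, rec$sex, rec$age)
  eps <- 1e-6
  mk <- function(bmi) { r <- rec; r$weight <- bmi * (r$height / 100)^2; r }
  for (case in list(list(cut$p85 - eps, "ideal"),
                    list(cut$p85, "intermediate"),
                    list(cut$p95, "intermediate"),
                    list(cut$p95 + eps, "poor"))) {
    expect_equal(as.character(cvh_profile(mk(case[[1]]), REFS)$bmi), case[[2]])
  }
  # DBP percentile cut-offs for this record sit below the absolute 80 mmHg
  # rule, so the percentile bands alone govern
  bpc <- bp_cutoffs(REFS, rec$sex, rec$age, rec$height)
  stopifnot(bpc$dbp_p95 < 80)
  mkbp <- function(dbp) { r <- rec; r$dbp <- dbp; r }
  expect_equal(as.character(cvh_profile(mkbp(bpc$dbp_p90 - eps), REFS)$bp), "ideal")
  expect_equal(as.character(cvh_profile(mkbp(bpc$dbp_p90), REFS)$bp), "intermediate")
  expect_equal(as.character(cvh_profile(mkbp(bpc$dbp_p95), REFS)$bp), "intermediate")
  expect_equal(as.character(cvh_profile(mkbp(bpc$dbp_p95 + eps), REFS)$bp), "poor")
})

test_that("composite scores, categories and flags over all status combinations", {
  rec <- ideal_record()
  cut <- bmi_cutoffs(REFS, rec$sex, rec$age)
  bpc <- bp_cutoffs(REFS, rec$sex, rec$age, rec$height)
  # representative input values realizing each status per metric
  vals <- list(
    smoking = list(poor = TRUE, ideal = FALSE),
    bmi = list(poor = cut$p95 + 1, intermediate = (cut$p85 + cut$p95) / 2,
               ideal = cut$p85 - 2),
    physical_activity = list(poor = 0, intermediate = 30, ideal = 90),
    diet = list(poor = 0, intermediate = 3, ideal = 5),
    bp = list(poor = bpc$sbp_p95 + 2, intermediate = bpc$sbp_p90 + 0.5,
              ideal = bpc$sbp_p90 - 10),
    tc = list(poor = 220, intermediate = 180, ideal = 150),
    fbg = list(poor = 130, intermediate = 110, ideal = 90)
  )
  combos <- expand.grid(smoking = c("poor", "ideal"),
                        bmi = c("poor", "intermediate", "ideal"),
                        physical_activity = c("poor", "intermediate", "ideal"),
                        diet = c("poor", "intermediate", "ideal"),
                        bp = c("poor", "intermediate", "ideal"),
                        tc = c("poor", "intermediate", "ideal"),
                        fbg = c("poor", "intermediate", "ideal"),
                        stringsAsFactors = FALSE)
  n <- nrow(combos)  # 2 * 3^6 = 1458
  data <- ideal_record(n)
  data$smoked_past_30d <- unlist(vals$smoking[combos$smoking])
  data$weight <- unlist(vals$bmi[combos$bmi]) * (data$height / 100)^2
  data$mvpa_minutes_per_day <- unlist(vals$physical_activity[combos$physical_activity])
  dietn <- unlist(vals$diet[combos$diet])
  data$diet_fruit_veg <- ifelse(dietn >= 1, 2, 0)
  data$diet_aquatic <- ifelse(dietn >= 2, 2, 0)
  data$diet_fried_fast <- ifelse(dietn >= 3, 0.5, 3)
  data$diet_ssb <- ifelse(dietn >= 4, 0, 2)
  data$diet_bean_dairy <- ifelse(dietn >= 5, 2, 0)
  data$sbp <- unlist(vals$bp[combos$bp])
  data$tc <- unlist(vals$tc[combos$tc])
  data$fbg <- unlist(vals$fbg[combos$fbg])

  prof <- cvh_profile(data, REFS)
  expect_true(all(prof$valid))
  # realized statuses are the intended ones
  for (m in names(vals)) expect_equal(as.character(prof[[m]]), combos[[m]])
  # score decomposition and ranges
  expect_equal(prof$cvh_score, prof$behavior_score + prof$factor_score)
  ideal_n <- rowSums(sapply(names(vals), function(m) combos[[m]] == "ideal"))
  expect_equal(prof$cvh_score, unname(ideal_n))
  # category partition {0-2 / 3-5 / 6-7}: exactly one category each
  want <- ifelse(prof$cvh_score >= 6, "ideal",
                 ifelse(prof$cvh_score >= 3, "intermediate", "poor"))
  expect_equal(as.character(prof$cvh_category), want)
  expect_equal(prof$ideal_behaviors, prof$behavior_score >= 3)
  expect_equal(prof$ideal_factors, prof$factor_score == 3)
})

test_that("a missing metric invalidates the profile without an error", {
  data <- ideal_record(3)
  data$tc[2] <- NA
  prof <- cvh_profile(data, REFS)
  expect_equal(prof$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(prof$cvh_score[2]))
  expect_equal(metric_missing_reasons(data, REFS)[2], "metric-missing:tc")
})

test_that("worsening any single input never improves the score", {
  set.seed(41)
  base <- ideal_record(1)
  worse <- list(
    function(r) { r$tc <- r$tc + 40; r },
    function(r) { r$fbg <- r$fbg + 20; r },
    function(r) { r$sbp <- r$sbp + 25; r },
    function(r) { r$dbp <- r$dbp + 26; r },
    function(r) { r$weight <- r$weight * 1.35; r },
    function(r) { r$mvpa_minutes_per_day <- pmax(0, r$mvpa_minutes_per_day - 40); r },
    function(r) { r$diet_ssb <- 3; r },
    function(r) { r$smoked_past_30d <- TRUE; r }
  )
  for (i in 1:60) {
    r <- base
    r$tc <- runif(1, 140, 210); r$fbg <- runif(1, 80, 130)
    r$sbp <- runif(1, 90, 125); r$mvpa_minutes_per_day <- runif(1, 0, 90)
    s0 <- cvh_profile(r, REFS)$cvh_score
    for (w in worse) {
      s1 <- cvh_profile(w(r), REFS)$cvh_score
      expect_lte(s1, s0)
    }
  }
})

test_that("profile agrees with the independent oracle on randomized records", {
  set.seed(99)
  n <- 10000
  data <- ideal_record(n)
  data$sex <- sample(c("male", "female"), n, TRUE)
  data$age <- runif(n, 6, 17.99)
  data$height <- value_at_percentile(REFS$height_ref, data$sex, data$age,
                                     runif(n, 2, 98))
  bmi <- value_at_percentile(REFS$bmi_ref, data$sex, data$age,
                             runif(n, 2, 98))
  data$weight <- bmi * (data$height / 100)^2
  data$sbp <- runif(n, 85, 135)
  data$dbp <- runif(n, 50, 85)
  data$tc <- runif(n, 120, 230)
  data$fbg <- runif(n, 70, 140)
  data$smoked_past_30d <- runif(n) < 0.3
  data$mvpa_minutes_per_day <- sample(c(0, 15, 59, 60, 61, 120), n, TRUE)
  data$diet_fruit_veg <- sample(c(0, 0.5, 1, 2), n, TRUE)
  data$diet_aquatic <- sample(c(0, 1, 3), n, TRUE)
  data$diet_fried_fast <- sample(c(0, 1, 1.5, 3), n, TRUE)
  data$diet_ssb <- sample(c(0, 0.9, 1, 2), n, TRUE)
  data$diet_bean_dairy <- sample(c(0, 1, 2), n, TRUE)

  prof <- cvh_profile(data, REFS)
  cuts <- bmi_cutoffs(REFS, data$sex, data$age)
  bpcs <- bp_cutoffs(REFS, data$sex, data$age, data$height)
  idx <- sample(n, 1500)   # scalar oracle on a random subsample
  for (i in idx) {
    o <- oracle_classify(data[i, ], cuts$p85[i], cuts$p95[i], bpcs[i, ])
    expect_equal(as.character(unlist(prof[i, names(o$statuses)])),
                 unname(o$statuses))
    expect_equal(prof$cvh_score[i], o$cvh_score)
    expect_equal(as.character(prof$cvh_category[i]), o$category)
  }
})

test_that("mmol/L inputs convert to identical profiles", {
  data <- ideal_record(4)
  data$tc <- c(150, 180, 210, 169)
  data$fbg <- c(90, 105, 130, 99)
  mm <- data
  mm$tc <- data$tc / 38.67
  mm$fbg <- data$fbg / 18.016
  mm$tc <- to_mgdl(mm$tc, "tc", "mmol/L")
  mm$fbg <- to_mgdl(mm$fbg, "glucose", "mmol/L")
  expect_equal(cvh_profile(mm, REFS), cvh_profile(data, REFS))
})

test_that("derived covariates follow the documented definitions", {
  d <- ideal_record(6)
  d$smoke_env_days_per_week <- c(0, 1, 2, 0, NA, 0)
  d$parent_current_smoker <- c(FALSE, FALSE, FALSE, TRUE, TRUE, NA)
  d$age <- c(12, 12.9, 13, 8, 17, 10)
  d$sleep_hours_per_day <- c(9.5, 9.5, 9.5, 8.5, 9, 13)
  d$paternal_bmi <- c(23.9, 24.0, 27.99, 28, 31, NA)
  dc <- derive_covariates(d)
  expect_equal(dc$passive_smoking, c(FALSE, FALSE, TRUE, TRUE, TRUE, NA))
  # age 12 (and 12.9) use the 9-12 h band; 13 uses 8-10 h
  expect_equal(dc$sleep_adequate_flag, c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.character(dc$paternal_weight_status),
               c("normal", "overweight", "overweight", "obesity", "obesity", NA))
  expect_equal(as.character(dc$age_group),
               c("12-18", "12-18", "12-18", "6-11", "12-18", "6-11"))
  expect_equal(dc$fmp, 100 * d$fat_mass / d$weight)
})

test_that("FMP tertiles are computed within survey year", {
  d <- ideal_record(12)
  d$survey_year <- rep(c(2004, 2019), each = 6)
  # same fat-mass values in both years but shifted: tertile labels must be
  # assigned within year, so the two waves get identical tertile patterns
  d$fat_mass <- c(1:6, 101:106) / 10 * d$weight / 10
  dc <- derive_covariates(d)
  expect_equal(as.character(dc$fmp_tertile[1:6]),
               as.character(dc$fmp_tertile[7:12]))
  expect_equal(as.character(dc$fmp_tertile[1:6]),
               c("T1", "T1", "T2", "T2", "T3", "T3"))
})
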