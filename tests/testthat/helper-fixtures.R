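# Shared fixtures built in code.

REFS <- synthetic_reference_set()

# A metric-complete record with every metric comfortably ideal at the
# defaults; tests override single fields.
ideal_record <- function(n = 1, year = 2019, sex = "female", age = 10) {
  data.frame(
    id = sprintf("t%03d", seq_len(n)),
    survey_year = year, sex = sex, age = age,
    height = 140, weight = 30,          # BMI 15.3, well under p85
    fat_mass = 6,
    sbp = 95, dbp = 55,
    tc = 150, fbg = 85,
    smoked_past_30d = FALSE,
    mvpa_minutes_per_day = 90,
    diet_fruit_veg = 2, diet_aquatic = 2, diet_fried_fast = 0.5,
    diet_ssb = 0, diet_bean_dairy = 2,
    sedentary_hours_per_day = 1, sleep_hours_per_day = 10,
    smoke_env_days_per_week = 0, parent_current_smoker = FALSE,
    household_income = "middle",
    paternal_education = "college_plus", maternal_education = "college_plus",
    paternal_bmi = 22, maternal_bmi = 21,
    parental_cvd_history = FALSE, premature = FALSE, sexually_mature = FALSE,
    stringsAsFactors = FALSE
  )
}

# Exact conditional (permutation) p-value for the trend test: enumerates
# every 2 x k success allocation with the observed margins, weighting by the
# multivariate hypergeometric distribution.  Independent of the analytic
# normal approximation it checks.
perm_trend_p <- function(tab, scores = seq_len(ncol(tab))) {
  n_i <- colSums(tab)
  k1 <- sum(tab[1, ])
  zstat <- function(s1) {
    t2 <- rbind(s1, n_i - s1)
    pedcvh::cochran_armitage(t2, scores)$statistic
  }
  zobs <- abs(zstat(tab[1, ]))
  grids <- lapply(n_i, function(n) 0:n)
  combos <- expand.grid(grids)
  combos <- combos[rowSums(combos) == k1, , drop = FALSE]
  logp <- apply(combos, 1, function(s1) {
    sum(lchoose(n_i, s1)) - lchoose(sum(n_i), k1)
  })
  z <- apply(combos, 1, function(s1) abs(zstat(unlist(s1))))
  sum(exp(logp[z >= zobs - 1e-12]))
}

# A small MAR data generator used across the MI tests: outcome y depends on
# x1 and x2; x2 goes missing with probability depending on the observed x1
# and y only (hence MAR), at roughly the requested rate.
mar_toy <- function(n, b = c(-0.5, 0.8, 0.6), miss = 0.2, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- 0.4 * x1 + rnorm(n, sd = 0.9)
  y <- runif(n) < plogis(b[1] + b[2] * x1 + b[3] * x2)
  p_mis <- plogis(qlogis(miss) + 0.8 * x1 + 0.5 * (y - 0.5))
  p_mis <- p_mis * miss / mean(p_mis)
  full <- data.frame(y = y, x1 = x1, x2 = x2)
  obs <- full
  obs$x2[runif(n) < p_mis] <- NA
  list(full = full, obs = obs, beta = b)
}

# Independent straight-from-the-definitions classifier used as the scoring
# oracle: scalar, if/else, no shared code with cvh_profile beyond the
# numeric cut-offs it is handed.
oracle_classify <- function(rec, p85, p95, bpc) {
  smoking <- if (rec$smoked_past_30d) "poor" else "ideal"
  bmi <- rec$weight / (rec$height / 100)^2
  bmi_st <- if (bmi > p95) "poor" else if (bmi < p85) "ideal" else "intermediate"
  pa <- rec$mvpa_minutes_per_day
  pa_st <- if (pa == 0) "poor" else if (pa < 60) "intermediate" else "ideal"
  comps <- (rec$diet_fruit_veg >= 1) + (rec$diet_aquatic >= 1) +
    (rec$diet_fried_fast <= 1) + (rec$diet_ssb < 1) + (rec$diet_bean_dairy >= 1)
  diet_st <- if (comps >= 4) "ideal" else if (comps >= 2) "intermediate" else "poor"
  tc_st <- if (rec$tc >= 200) "poor" else if (rec$tc >= 170) "intermediate" else "ideal"
  fbg_st <- if (rec$fbg >= 126) "poor" else if (rec$fbg >= 100) "intermediate" else "ideal"
  bp_st <- if (rec$sbp > bpc$sbp_p95 || rec$dbp > bpc$dbp_p95) "poor"
    else if (rec$sbp >= bpc$sbp_p90 || rec$dbp >= bpc$dbp_p90 ||
             rec$sbp >= 120 || rec$dbp >= 80) "intermediate"
    else "ideal"
  st <- c(smoking = smoking, bmi = bmi_st, physical_activity = pa_st,
          diet = diet_st, bp = bp_st, tc = tc_st, fbg = fbg_st)
  score <- sum(st == "ideal")
  beh <- sum(st[c("smoking", "bmi", "physical_activity", "diet")] == "ideal")
  fac <- sum(st[c("bp", "tc", "fbg")] == "ideal")
  cat_ <- if (score >= 6) "ideal" else if (score >= 3) "intermediate" else "poor"
  list(statuses = st, cvh_score = score, behavior_score = beh,
       factor_score = fac, category = cat_)
}
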