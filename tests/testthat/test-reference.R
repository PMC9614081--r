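test_that("LMS z-score formula: identity, linear and log branches", {
  expect_equal(lms_zscore(18, l = -1.5, m = 18, s = 0.1), 0)
  expect_equal(lms_zscore(18, l = 0, m = 18, s = 0.1), 0)
  # L = 1 reduces to (x - M) / (M * S)
  expect_equal(lms_zscore(19.8, l = 1, m = 18, s = 0.1), 1.0)
  # L = 0 log branch closed form
  expect_equal(lms_zscore(18 * exp(0.1), l = 0, m = 18, s = 0.1), 1.0)
  expect_error(lms_zscore(-1, 1, 18, 0.1), "positive")
  expect_error(lms_zscore(18, 1, 18, -0.1), "positive")
})

test_that("fixture TSVs round-trip through the loader", {
  dir <- system.file("extdata", package = "pedcvh")
  rs <- load_reference_set(file.path(dir, "synthetic_bmi_lms.tsv"),
                           file.path(dir, "synthetic_bp_reference.tsv"),
                           file.path(dir, "synthetic_height_lms.tsv"))
  expect_s3_class(rs, "reference_set")
  expect_setequal(unique(rs$bmi_ref$sex), c("male", "female"))
  expect_equal(range(rs$bmi_ref$age_years), c(6, 18))
  expect_equal(range(rs$bp_ref$ages), c(6, 18))
  # identical to the in-memory constructor
  mem <- synthetic_reference_set()
  expect_equal(rs$bmi_ref$M, mem$bmi_ref$M)
  expect_equal(rs$bp_ref$table$sbp_p95, mem$bp_ref$table$sbp_p95)
})

test_that("loader rejects malformed reference tables", {
  bmi <- pedcvh:::synthetic_lms_curves("bmi")
  hei <- pedcvh:::synthetic_lms_curves("height")
  bp <- pedcvh:::synthetic_bp_grid()

  bad <- bmi; names(bad)[3] <- "lambda"
  expect_error(reference_set(bad, bp, hei), "missing column")
  bad <- bmi; bad$S[4] <- 0
  expect_error(reference_set(bad, bp, hei), "non-positive M or S")
  bad <- bmi; bad$age_years[2] <- bad$age_years[1]
  expect_error(reference_set(bad, bp, hei), "strictly increasing")
  # drop one BP cell -> incomplete grid, error names a cell
  hole <- bp[!(bp$sex == "female" & bp$age_years == 12 &
                 bp$height_band == "P50-P75"), ]
  expect_error(reference_set(bmi, hole, hei), "incomplete grid")
  bad <- bp; bad$sbp_p95[10] <- bad$sbp_p90[10] - 1
  expect_error(reference_set(bmi, bad, hei), "p95 < p90")
})

test_that("value_at_percentile: median identity, inverse property, monotonicity", {
  for (sx in c("male", "female")) {
    # p = 50 at a grid age returns M exactly
    grid <- REFS$bmi_ref[REFS$bmi_ref$sex == sx, ]
    expect_equal(value_at_percentile(REFS$bmi_ref, sx, grid$age_years, 50),
                 grid$M, tolerance = 1e-12)
    for (age in c(6, 9.25, 13.8, 18)) {
      ps <- c(1, 5, 25, 50, 75, 85, 95, 99)
      v <- vapply(ps, function(p)
        value_at_percentile(REFS$bmi_ref, sx, age, p), numeric(1))
      expect_true(all(diff(v) > 0))  # strictly increasing in p
      back <- vapply(v, function(x) percentile_of(REFS$bmi_ref, sx, age, x),
                     numeric(1))
      expect_equal(back, ps, tolerance = 1e-9)
    }
  }
  expect_error(value_at_percentile(REFS$bmi_ref, "male", 5, 50), "coverage")
  expect_error(value_at_percentile(REFS$bmi_ref, "male", 10, 0), "0, 100")
})

test_that("age midway between grid points uses averaged L, M, S", {
  tab <- REFS$bmi_ref[REFS$bmi_ref$sex == "female", ]
  i <- match(10, tab$age_years); j <- match(10.5, tab$age_years)
  lmid <- (tab$L[i] + tab$L[j]) / 2
  mmid <- (tab$M[i] + tab$M[j]) / 2
  smid <- (tab$S[i] + tab$S[j]) / 2
  want <- mmid * (1 + lmid * smid * qnorm(0.85))^(1 / lmid)
  expect_equal(value_at_percentile(REFS$bmi_ref, "female", 10.25, 85), want,
               tolerance = 1e-12)
})

test_that("bmi_cutoffs match a hand evaluation and keep p85 < p95 everywhere", {
  tab <- REFS$bmi_ref[REFS$bmi_ref$sex == "female", ]
  r <- tab[tab$age_years == 10, ]
  hand <- function(p) r$M * (1 + r$L * r$S * qnorm(p / 100))^(1 / r$L)
  cut <- bmi_cutoffs(REFS, "female", 10)
  expect_equal(cut$p85, hand(85), tolerance = 1e-12)
  expect_equal(cut$p95, hand(95), tolerance = 1e-12)
  grid <- expand.grid(sex = c("male", "female"), age = seq(6, 18, 0.5),
                      stringsAsFactors = FALSE)
  cc <- bmi_cutoffs(REFS, grid$sex, grid$age)
  expect_true(all(cc$p85 < cc$p95))
  expect_error(bmi_cutoffs(REFS, "male", 5), "coverage")
})

test_that("fixture BMI cut-offs are non-decreasing with age", {
  for (sx in c("male", "female")) {
    cc <- bmi_cutoffs(REFS, sx, seq(6, 18, 0.5))
    expect_true(all(diff(cc$p85) > -1e-9))
    expect_true(all(diff(cc$p95) > -1e-9))
  }
})

test_that("bp_cutoffs: band lookup, tie rule, p95 >= p90", {
  # a boy exactly at the median height: percentile 50 ties to the upper
  # band P50-P75 by the left-closed rule
  h50 <- value_at_percentile(REFS$height_ref, "male", 12, 50)
  cut <- bp_cutoffs(REFS, "male", 12, h50)
  expect_equal(cut$height_band, "P50-P75")
  tab <- REFS$bp_ref$table
  cell <- tab[tab$sex == "male" & tab$age_years == 12 &
                tab$height_band == "P50-P75", ]
  expect_equal(cut$sbp_p90, cell$sbp_p90)
  expect_equal(cut$dbp_p95, cell$dbp_p95)
  # fractional ages truncate to completed years: the returned cell is the
  # age-12 row at whatever band the age-12.9 height percentile assigns
  h <- value_at_percentile(REFS$height_ref, "male", 12.9, 40)
  cut129 <- bp_cutoffs(REFS, "male", 12.9, h)
  cell129 <- tab[tab$sex == "male" & tab$age_years == 12 &
                   tab$height_band == cut129$height_band, ]
  expect_equal(cut129$sbp_p90, cell129$sbp_p90)
  expect_equal(cut129$dbp_p90, cell129$dbp_p90)
  expect_true(all(tab$sbp_p95 >= tab$sbp_p90 & tab$dbp_p95 >= tab$dbp_p90))
  expect_error(bp_cutoffs(REFS, "male", 19.3, 170), "coverage")
  expect_error(bp_cutoffs(REFS, "male", 12, -3), "positive")
})

test_that("extreme heights land in the outer bands", {
  tiny <- value_at_percentile(REFS$height_ref, "female", 9, 1)
  tall <- value_at_percentile(REFS$height_ref, "female", 9, 99)
  expect_equal(bp_cutoffs(REFS, "female", 9, tiny)$height_band, "<P5")
  expect_equal(bp_cutoffs(REFS, "female", 9, tall)$height_band, ">=P95")
})
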