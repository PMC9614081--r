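# Growth and blood-pressure reference standards.
#
# BMI-for-age and height-for-age references are represented with the LMS
# system (Box-Cox power L, median M, coefficient of variation S on an age
# grid, one curve per sex).  Blood pressure references are a complete
# sex x integer-age x height-band grid of the 90th/95th percentiles of SBP
# and DBP, the layout in which pediatric BP standards are published.

HEIGHT_BAND_EDGES_DEFAULT <- c(5, 25, 50, 75, 95)

height_band_labels <- function(edges = HEIGHT_BAND_EDGES_DEFAULT) {
  k <- length(edges)
  c(paste0("<P", edges[1]),
    paste0("P", edges[-k], "-P", edges[-1]),
    paste0(">=P", edges[k]))
}

#' LMS z-score
#'
#' Converts a measurement to a z-score under the LMS (Box-Cox) reference
#' model: z = ((x/M)^L - 1) / (L*S) for L != 0 and z = log(x/M)/S for L = 0.
#'
#' @param x positive measurement (e.g. BMI in kg/m2, height in cm).
#' @param l,m,s LMS parameters; m > 0, s > 0.
#' @return numeric z-score, vectorized over all arguments.
#' @examples
#' lms_zscore(19.8, l = 1, m = 18, s = 0.1)  # exactly 1
#' @export
lms_zscore <- function(x, l, m, s) {
  n <- max(length(x), length(l), length(m), length(s))
  x <- rep_len(x, n); l <- rep_len(l, n); m <- rep_len(m, n); s <- rep_len(s, n)
  if (any(!is.finite(x) | x <= 0)) stop_pedcvh("lms_zscore: x must be positive")
  if (any(m <= 0) || any(s <= 0)) stop_pedcvh("lms_zscore: M and S must be positive")
  z <- ifelse(abs(l) < 1e-12,
              log(x / m) / s,
              ((x / m)^l - 1) / (l * s))
  as.numeric(z)
}

#' Inverse LMS: measurement at a z-score
#'
#' @param z z-score.
#' @param l,m,s LMS parameters.
#' @return measurement on the original scale.
#' @export
lms_value <- function(z, l, m, s) {
  n <- max(length(z), length(l), length(m), length(s))
  z <- rep_len(z, n); l <- rep_len(l, n); m <- rep_len(m, n); s <- rep_len(s, n)
  ifelse(abs(l) < 1e-12,
         m * exp(s * z),
         m * (1 + l * s * z)^(1 / l))
}

new_lms_reference <- function(df, what = "lms") {
  req <- c("sex", "age_years", "L", "M", "S")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_pedcvh("%s table: missing column(s) %s", what, paste(miss, collapse = ", "))
  }
  df$sex <- as.character(df$sex)
  check_sex(df$sex)
  for (sx in SEX_LEVELS) {
    sub <- df[df$sex == sx, ]
    if (!nrow(sub)) stop_pedcvh("%s table: sex '%s' absent", what, sx)
    if (is.unsorted(sub$age_years, strictly = TRUE)) {
      stop_pedcvh("%s table (%s): age grid not strictly increasing", what, sx)
    }
    if (any(sub$M <= 0) || any(sub$S <= 0)) {
      bad <- which(sub$M <= 0 | sub$S <= 0)[1]
      stop_pedcvh("%s table (%s): non-positive M or S at age %.2f",
                  what, sx, sub$age_years[bad])
    }
  }
  structure(df[order(df$sex, df$age_years), req, drop = FALSE],
            class = c("lms_reference", "data.frame"))
}

interp_lms <- function(ref, sex, age) {
  sex <- check_sex(sex)
  n <- max(length(sex), length(age))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  out <- data.frame(L = numeric(n), M = numeric(n), S = numeric(n))
  for (sx in unique(sex)) {
    sub <- ref[ref$sex == sx, ]
    idx <- which(sex == sx)
    a <- age[idx]
    if (any(a < min(sub$age_years) - 1e-9 | a > max(sub$age_years) + 1e-9)) {
      stop_pedcvh("age %.2f outside reference coverage [%g, %g]; no extrapolation",
                  a[which(a < min(sub$age_years) | a > max(sub$age_years))[1]],
                  min(sub$age_years), max(sub$age_years))
    }
    out$L[idx] <- stats::approx(sub$age_years, sub$L, a, rule = 1)$y
    out$M[idx] <- stats::approx(sub$age_years, sub$M, a, rule = 1)$y
    out$S[idx] <- stats::approx(sub$age_years, sub$S, a, rule = 1)$y
  }
  out
}

new_bp_reference <- function(df, band_edges = HEIGHT_BAND_EDGES_DEFAULT) {
  req <- c("sex", "age_years", "height_band",
           "sbp_p90", "sbp_p95", "dbp_p90", "dbp_p95")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_pedcvh("bp table: missing column(s) %s", paste(miss, collapse = ", "))
  }
  df$sex <- as.character(df$sex)
  df$height_band <- as.character(df$height_band)
  check_sex(df$sex)
  bands <- height_band_labels(band_edges)
  if (!all(df$height_band %in% bands)) {
    stop_pedcvh("bp table: unknown height band '%s' (expected %s)",
                setdiff(df$height_band, bands)[1], paste(bands, collapse = ", "))
  }
  if (any(df$sbp_p95 < df$sbp_p90) || any(df$dbp_p95 < df$dbp_p90)) {
    stop_pedcvh("bp table: p95 < p90 in at least one cell")
  }
  ages <- sort(unique(df$age_years))
  want <- expand.grid(sex = SEX_LEVELS, age_years = ages, height_band = bands,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$sex, d$age_years, d$height_band)
  missing_cells <- setdiff(key(want), key(df))
  if (length(missing_cells)) {
    stop_pedcvh("bp table: incomplete grid, missing cell(s) e.g. %s",
                missing_cells[1])
  }
  if (anyDuplicated(key(df))) stop_pedcvh("bp table: duplicated grid cell")
  structure(list(table = df[req], band_edges = band_edges, ages = ages),
            class = "bp_reference")
}

#' Assemble a validated reference set
#'
#' Bundles the BMI LMS reference, the height LMS reference (used to place a
#' child in a height band) and the BP percentile grid, checking all
#' structural invariants.
#'
#' @param bmi,height data frames with columns sex, age_years, L, M, S.
#' @param bp data frame with columns sex, age_years, height_band, sbp_p90,
#'   sbp_p95, dbp_p90, dbp_p95 covering the full sex x age x band grid.
#' @param height_band_edges height percentile band edges (default 5, 25, 50,
#'   75, 95); bands are half-open, closed on the left, a percentile exactly
#'   at an edge belongs to the upper band.
#' @param provenance free-text label recorded with the set.
#' @return object of class `reference_set`.
#' @seealso [load_reference_set()], [synthetic_reference_set()]
#' @export
reference_set <- function(bmi, bp, height,
                          height_band_edges = HEIGHT_BAND_EDGES_DEFAULT,
                          provenance = "user-supplied") {
  rs <- structure(list(
    bmi_ref = new_lms_reference(bmi, "bmi"),
    height_ref = new_lms_reference(height, "height"),
    bp_ref = new_bp_reference(bp, height_band_edges),
    band_edges = height_band_edges,
    provenance = provenance
  ), class = "reference_set")
  rs
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set>", x$provenance, "\n")
  cat("  BMI/height LMS ages:",
      paste(range(x$bmi_ref$age_years), collapse = "-"), "y\n")
  cat("  BP grid ages:", paste(range(x$bp_ref$ages), collapse = "-"),
      "y x", length(height_band_labels(x$band_edges)), "height bands\n")
  invisible(x)
}

#' Load a reference set from TSV files
#'
#' Reads the documented tab-separated layouts: LMS tables with columns
#' `sex age_years L M S`, BP tables with columns
#' `sex age_years height_band sbp_p90 sbp_p95 dbp_p90 dbp_p95`.
#'
#' @param bmi_path,bp_path,height_path file paths.
#' @inheritParams reference_set
#' @return a `reference_set`.
#' @export
load_reference_set <- function(bmi_path, bp_path, height_path,
                               height_band_edges = HEIGHT_BAND_EDGES_DEFAULT,
                               provenance = NULL) {
  read1 <- function(p) {
    if (!file.exists(p)) stop_pedcvh("reference file not found: %s", p)
    utils::read.delim(p, sep = "\t", stringsAsFactors = FALSE)
  }
  reference_set(read1(bmi_path), read1(bp_path), read1(height_path),
                height_band_edges = height_band_edges,
                provenance = provenance %||% paste("loaded from", dirname(bmi_path)))
}

#' Measurement value at a reference percentile
#'
#' Inverts the LMS transform at the standard-normal quantile of `p`,
#' interpolating L, M and S linearly in age between grid points.
#'
#' @param ref an `lms_reference` (a component of a [reference_set()]).
#' @param sex "male" or "female".
#' @param age age in years, inside the grid (no extrapolation).
#' @param p percentile in (0, 100).
#' @return measurement on the reference's scale.
#' @export
value_at_percentile <- function(ref, sex, age, p) {
  if (any(p <= 0 | p >= 100)) stop_pedcvh("percentile must be in (0, 100)")
  par <- interp_lms(ref, sex, age)
  lms_value(stats::qnorm(p / 100), par$L, par$M, par$S)
}

#' Reference percentile of a measurement
#'
#' @inheritParams value_at_percentile
#' @param x measurement.
#' @return percentile in (0, 100).
#' @export
percentile_of <- function(ref, sex, age, x) {
  par <- interp_lms(ref, sex, age)
  100 * stats::pnorm(lms_zscore(x, par$L, par$M, par$S))
}

#' BMI classification cut-offs (85th and 95th percentiles)
#'
#' @param refs a [reference_set()].
#' @param sex,age vectors (recycled).
#' @return data frame with columns p85 and p95 in kg/m2.
#' @export
bmi_cutoffs <- function(refs, sex, age) {
  data.frame(p85 = value_at_percentile(refs$bmi_ref, sex, age, 85),
             p95 = value_at_percentile(refs$bmi_ref, sex, age, 95))
}

assign_height_band <- function(refs, sex, age, height) {
  pct <- percentile_of(refs$height_ref, sex, age, height)
  labs <- height_band_labels(refs$band_edges)
  # findInterval: percentile exactly at an edge falls in the upper band
  labs[findInterval(pct, refs$band_edges) + 1L]
}

#' Blood-pressure cut-offs for a child
#'
#' Height is converted to a height percentile via the height reference,
#' mapped to a height band (left-closed intervals; a percentile exactly at a
#' band edge goes to the upper band) and the matching cell of the BP grid is
#' returned.  Age is truncated to completed integer years.
#'
#' @inheritParams bmi_cutoffs
#' @param height height in cm.
#' @return data frame with sbp_p90, sbp_p95, dbp_p90, dbp_p95 (mmHg) and the
#'   assigned height_band.
#' @export
bp_cutoffs <- function(refs, sex, age, height) {
  n <- max(length(sex), length(age), length(height))
  sex <- rep_len(check_sex(sex), n)
  age <- rep_len(age, n); height <- rep_len(height, n)
  if (any(height <= 0)) stop_pedcvh("height must be positive")
  age_i <- floor(age)
  rng <- range(refs$bp_ref$ages)
  if (any(age_i < rng[1] | age_i > rng[2])) {
    stop_pedcvh("age %d outside BP reference coverage [%d, %d]",
                age_i[which(age_i < rng[1] | age_i > rng[2])[1]], rng[1], rng[2])
  }
  band <- assign_height_band(refs, sex, age, height)
  tab <- refs$bp_ref$table
  idx <- match(paste(sex, age_i, band),
               paste(tab$sex, tab$age_years, tab$height_band))
  out <- tab[idx, c("sbp_p90", "sbp_p95", "dbp_p90", "dbp_p95")]
  out$height_band <- band
  rownames(out) <- NULL
  out
}

# ---- synthetic fixture reference -------------------------------------------

# Smooth, plausible LMS curves for urban Chinese school-age children.  These
# are synthetic stand-ins for the national reference publications (which are
# external and not redistributable here); they are labelled as such and are
# used for fixtures, examples and the cohort generator's anthropometry model.
synthetic_lms_curves <- function(which = c("bmi", "height"),
                                 ages = seq(6, 18, by = 0.5)) {
  which <- match.arg(which)
  rows <- list()
  for (sx in SEX_LEVELS) {
    if (which == "height") {
      if (sx == "male") {
        m <- 117 + 55 / (1 + exp(-(ages - 12.5) / 2.1))
        l <- rep(1, length(ages)); s <- rep(0.042, length(ages))
      } else {
        m <- 116 + 45 / (1 + exp(-(ages - 11.0) / 1.9))
        l <- rep(1, length(ages)); s <- rep(0.040, length(ages))
      }
    } else {
      if (sx == "male") {
        m <- 15.3 + 6.6 / (1 + exp(-(ages - 13.0) / 2.6))
        l <- -1.6 + 0.04 * (ages - 6)
        s <- 0.125 - 0.002 * (ages - 6)
      } else {
        m <- 15.1 + 6.0 / (1 + exp(-(ages - 12.3) / 2.4))
        l <- -1.4 + 0.035 * (ages - 6)
        s <- 0.115 - 0.0015 * (ages - 6)
      }
    }
    rows[[sx]] <- data.frame(sex = sx, age_years = ages,
                             L = round(l, 4), M = round(m, 2), S = round(s, 4))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Normal-quantile parameterization: each BP grid cell stores the 90th/95th
# percentiles of a N(mu, sd) distribution, so the generator can draw BP
# values whose exceedance probabilities over the grid are known exactly.
synthetic_bp_normal_params <- function(sex, age, band_index) {
  male <- as.numeric(sex == "male")
  list(
    sbp_mu = 95 + 1.45 * age + 1.1 * (band_index - 3.5) + 1.5 * male,
    sbp_sd = rep_len(10.5, length(age)),
    dbp_mu = 57 + 0.65 * age + 0.45 * (band_index - 3.5) + 0.5 * male,
    dbp_sd = rep_len(7.5, length(age))
  )
}

synthetic_bp_grid <- function(ages = 6:18,
                              band_edges = HEIGHT_BAND_EDGES_DEFAULT) {
  bands <- height_band_labels(band_edges)
  g <- expand.grid(sex = SEX_LEVELS, age_years = ages,
                   height_band = bands, stringsAsFactors = FALSE)
  bi <- match(g$height_band, bands)
  p <- synthetic_bp_normal_params(g$sex, g$age_years, bi)
  z90 <- stats::qnorm(0.90); z95 <- stats::qnorm(0.95)
  g$sbp_p90 <- round(p$sbp_mu + z90 * p$sbp_sd, 1)
  g$sbp_p95 <- round(p$sbp_mu + z95 * p$sbp_sd, 1)
  g$dbp_p90 <- round(p$dbp_mu + z90 * p$dbp_sd, 1)
  g$dbp_p95 <- round(p$dbp_mu + z95 * p$dbp_sd, 1)
  g[order(g$sex, g$age_years, match(g$height_band, bands)), ]
}

#' Synthetic reference set
#'
#' Builds the package's synthetic-but-realistic growth and BP reference
#' tables in memory: smooth LMS curves for BMI-for-age and height-for-age
#' (ages 6-18 by 0.5 y, both sexes) and a complete sex x age x height-band
#' BP percentile grid.  These stand in for national reference publications,
#' which are external; they are NOT the published Chinese reference values.
#'
#' @return a `reference_set` with provenance "synthetic".
#' @export
synthetic_reference_set <- function() {
  reference_set(synthetic_lms_curves("bmi"),
                synthetic_bp_grid(),
                synthetic_lms_curves("height"),
                provenance = "synthetic")
}

#' Write the synthetic reference tables as TSV files
#'
#' @param dir output directory.
#' @return invisibly, the three file paths.
#' @export
write_synthetic_reference <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("synthetic_bmi_lms.tsv", "synthetic_bp_reference.tsv",
                            "synthetic_height_lms.tsv"))
  utils::write.table(synthetic_lms_curves("bmi"), paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(synthetic_bp_grid(), paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(synthetic_lms_curves("height"), paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
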