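# Survey-trend statistics: proportion intervals, the Cochran-Armitage test
# for trend in a binary outcome over ordered survey waves, and Table-style
# descriptive comparisons (ANOVA / chi-squared).

#' Wilson score interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @param method "wilson" (default) or "clopper-pearson".
#' @return data frame with k, n, proportion, lower, upper.
#' @export
prevalence_ci <- function(k, n, level = 0.95, method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (any(n <= 0)) stop_pedcvh("prevalence_ci: n must be positive")
  if (any(k < 0 | k > n)) stop_pedcvh("prevalence_ci: need 0 <= k <= n")
  p <- k / n
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- pmax(0, centre - half)
    hi <- pmin(1, centre + half)
  } else {
    a <- 1 - level
    lo <- ifelse(k == 0, 0, stats::qbeta(a / 2, k, n - k + 1))
    hi <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 1, n - k))
  }
  data.frame(k = k, n = n, proportion = p, lower = lo, upper = hi)
}

#' Cochran-Armitage test for trend
#'
#' Tests for a linear trend in a binary outcome across k ordered groups.
#' The statistic is
#' Z = sum_i s_i (n1i - ni * pbar) /
#'     sqrt(pbar (1 - pbar) (sum_i ni s_i^2 - (sum_i ni s_i)^2 / N)),
#' where n1i are successes, ni group totals, s_i the group scores and pbar
#' the overall success fraction; the two-sided p-value is normal.
#'
#' @param tab 2 x k matrix of counts, row 1 = successes, row 2 = failures;
#'   columns are the ordered groups (e.g. survey waves).
#' @param scores group scores; default 1..k (survey order).  Calendar years
#'   may be supplied instead.
#' @return list with statistic (Z), p.value, scores, degenerate flag.
#' @export
cochran_armitage <- function(tab, scores = seq_len(ncol(tab))) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2 || ncol(tab) < 2) stop_pedcvh("need a 2 x k table, k >= 2")
  if (any(tab < 0)) stop_pedcvh("counts must be non-negative")
  if (length(scores) != ncol(tab)) stop_pedcvh("scores length must match columns")
  n_i <- colSums(tab)
  if (any(n_i == 0)) stop_pedcvh("empty group column")
  N <- sum(n_i)
  k1 <- sum(tab[1, ])
  pbar <- k1 / N
  out <- list(scores = scores, degenerate = FALSE)
  varpart <- pbar * (1 - pbar) * (sum(n_i * scores^2) - sum(n_i * scores)^2 / N)
  if (pbar %in% c(0, 1) || varpart <= 0) {
    out$statistic <- 0
    out$p.value <- 1
    out$degenerate <- TRUE
  } else {
    num <- sum(scores * (tab[1, ] - n_i * pbar))
    out$statistic <- num / sqrt(varpart)
    out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  }
  class(out) <- "ca_trend_test"
  out
}

#' @export
print.ca_trend_test <- function(x, ...) {
  cat("Cochran-Armitage trend test: Z =", format(x$statistic, digits = 4),
      ", two-sided p =", format.pval(x$p.value, digits = 4), "\n")
  if (x$degenerate) cat("  (degenerate table: no variation)\n")
  invisible(x)
}

#' Trend test from a status vector and ordered group labels
#'
#' Convenience wrapper: tabulates `success` over the ordered levels of
#' `group` and runs [cochran_armitage()].
#'
#' @param success logical vector.
#' @param group group labels (coerced to factor; level order = score order).
#' @param scores optional explicit scores.
#' @return a `ca_trend_test`.
#' @export
trend_test <- function(success, group, scores = NULL) {
  group <- as.factor(group)
  keep <- !is.na(success) & !is.na(group)
  tab <- rbind(tapply(success[keep], group[keep], sum),
               tapply(!success[keep], group[keep], sum))
  cochran_armitage(tab, scores %||% seq_len(ncol(tab)))
}

#' Descriptive comparison of characteristics across groups
#'
#' Mirrors a baseline-characteristics table: continuous variables as mean
#' (SD) per group with a one-way ANOVA p-value; categorical variables as
#' N (%) per group with a Pearson chi-squared p-value (no continuity
#' correction by default).
#'
#' @param data data frame.
#' @param group name of the grouping column.
#' @param vars character vector of columns to describe (default: all except
#'   `group` and id-like columns).
#' @param correct logical, Yates continuity correction for 2 x 2 tables.
#' @return data frame with variable, level, one formatted column per group,
#'   and p-value.
#' @export
describe_by_group <- function(data, group, vars = NULL, correct = FALSE) {
  g <- data[[group]]
  if (!is.factor(g)) g <- factor(g)
  counts <- table(g)
  if (any(counts == 0)) {
    warning("dropping empty group level(s): ",
            paste(names(counts)[counts == 0], collapse = ", "))
    g <- droplevels(g)
  }
  vars <- vars %||% setdiff(names(data), c(group, "id"))
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x)) {
      m <- tapply(x, g, mean, na.rm = TRUE)
      s <- tapply(x, g, stats::sd, na.rm = TRUE)
      p <- tryCatch(summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1],
                    error = function(e) NA_real_)
      cells <- sprintf("%.2f (%.2f)", m, s)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "mean (SD)",
        t(stats::setNames(cells, levels(g))), p = p, check.names = FALSE)
    } else {
      x <- factor(x)
      tab <- table(x, g)
      p <- if (nrow(tab) > 1 && all(dim(tab) >= 2)) {
        suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
      } else NA_real_
      pct <- prop.table(tab, 2) * 100
      for (lv in rownames(tab)) {
        cells <- sprintf("%d (%.1f)", tab[lv, ], pct[lv, ])
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv,
          t(stats::setNames(cells, levels(g))),
          p = if (lv == rownames(tab)[1]) p else NA_real_,
          check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
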