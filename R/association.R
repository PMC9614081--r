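# Multivariable logistic association models for ideal CVH, and the
# population attributable fraction (PAR) of overweight/obesity for each CVH
# factor.  The model-standardization PAR estimator is the primary one
# (predicted risk with the exposure set to its reference level, averaged
# over the observed covariate distribution); Levin's and Miettinen's
# closed-form 2x2 estimators are companions used for validation.

#' Multivariable logistic regression fit
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (the [stats::glm()] engine, deviance tolerance 1e-8), with Wald
#' confidence intervals on the odds-ratio scale.  Errors on rank-deficient
#' designs (naming the aliased columns) and flags likely separation.
#'
#' @param formula model formula with a binary (logical, 0/1 or two-level
#'   factor) outcome.
#' @param data data frame.
#' @param level confidence level for the Wald intervals.
#' @return object of class `cvh_logit`: list with `fit` (the glm),
#'   `table` (term, estimate, se, or, lower, upper, p), convergence info.
#' @export
fit_logistic <- function(formula, data, level = 0.95) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    fit0 <- stats::lm.fit(X, rep(0, nrow(X)))
    bad <- names(fit0$coefficients)[is.na(fit0$coefficients)]
    stop_pedcvh("rank-deficient design; aliased column(s): %s",
                paste(bad, collapse = ", "))
  }
  if (nrow(X) <= ncol(X)) stop_pedcvh("need more observations than parameters")
  fit <- stats::glm(formula, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separated <- !fit$converged || any(abs(beta) > 15)
  if (separated) {
    stop_pedcvh("separation suspected: non-converged fit or |coefficient| > 15",
                class = "pedcvh_separation")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se), or = exp(unname(beta)),
                    lower = exp(unname(beta - z * se)),
                    upper = exp(unname(beta + z * se)),
                    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))))
  structure(list(fit = fit, table = tab, converged = fit$converged,
                 iterations = fit$iter, deviance = fit$deviance),
            class = "cvh_logit")
}

#' @export
print.cvh_logit <- function(x, ...) {
  cat("<cvh_logit> deviance", format(x$deviance, digits = 6),
      "after", x$iterations, "IRLS iterations\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Model-standardized population attributable fraction
#'
#' AF = 1 - E[risk with exposure at reference] / E[observed risk]: the
#' fitted model predicts each subject's risk with the exposure column set
#' to its reference level; the mean of those counterfactual risks is
#' compared with the observed case fraction.  The CI is a seeded
#' nonparametric bootstrap (model refitted per resample).
#'
#' @param formula logistic model formula; must contain `exposure`.
#' @param data complete-case data frame for the model variables.
#' @param exposure name of a binary or factor exposure column; its first
#'   level (or FALSE) is the reference.
#' @param boot number of bootstrap resamples (0 skips the CI).
#' @param seed bootstrap seed.
#' @param level confidence level.
#' @return list with af, lower, upper, kind = "model_standardization".
#' @export
par_standardized <- function(formula, data, exposure, boot = 500, seed = 1,
                             level = 0.95) {
  vars <- all.vars(formula)
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  if (!exposure %in% vars) stop_pedcvh("exposure '%s' not in model", exposure)
  point <- function(d) {
    fit <- fit_logistic(formula, d)$fit
    y <- fit$y
    if (mean(y) == 0) stop_pedcvh("no cases; attributable fraction undefined")
    d0 <- d
    x <- d0[[exposure]]
    d0[[exposure]] <- if (is.logical(x)) FALSE
      else if (is.factor(x)) factor(levels(x)[1], levels = levels(x))
      else 0
    p0 <- stats::predict(fit, newdata = d0, type = "response")
    1 - mean(p0) / mean(y)
  }
  af <- point(data)
  lo <- hi <- NA_real_
  if (boot > 0) {
    set.seed(seed)
    reps <- vapply(seq_len(boot), function(i) {
      idx <- sample.int(nrow(data), replace = TRUE)
      tryCatch(point(data[idx, , drop = FALSE]), error = function(e) NA_real_)
    }, numeric(1))
    qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  list(af = af, lower = lo, upper = hi, kind = "model_standardization",
       exposure = exposure, n = nrow(data))
}

#' Closed-form attributable fractions from a 2x2 table
#'
#' Levin: p_e (RR - 1) / (1 + p_e (RR - 1)) with p_e the overall exposure
#' prevalence; Miettinen: p_c (RR - 1) / RR with p_c the exposure
#' prevalence among cases.  RR is the risk ratio.
#'
#' @param a exposed cases, `b` exposed non-cases, `c` unexposed cases,
#'   `d` unexposed non-cases.
#' @param b,c,d see `a`.
#' @param kind "levin" or "miettinen".
#' @return list with af, rr, kind.
#' @export
par_from_2x2 <- function(a, b, c, d, kind = c("levin", "miettinen")) {
  kind <- match.arg(kind)
  if (min(a + b, c + d) <= 0 || a + c <= 0) {
    stop_pedcvh("par_from_2x2: zero margin")
  }
  r1 <- a / (a + b)
  r0 <- c / (c + d)
  if (r0 == 0) stop_pedcvh("par_from_2x2: zero risk in the unexposed")
  rr <- r1 / r0
  af <- if (kind == "levin") {
    pe <- (a + b) / (a + b + c + d)
    pe * (rr - 1) / (1 + pe * (rr - 1))
  } else {
    pc <- a / (a + c)
    pc * (rr - 1) / rr
  }
  list(af = af, rr = rr, kind = kind)
}

#' Pooled association suite over imputed datasets
#'
#' Fits the logistic model on each imputed dataset, pools the coefficients
#' on the log-odds scale with Rubin's rules, and exponentiates to a pooled
#' odds-ratio table.  Optionally computes the model-standardized PAR per
#' imputation and pools it likewise (bootstrap within-imputation variance).
#'
#' @param imputations list of complete data frames (e.g.
#'   `impute_chained(...)$imputations`).
#' @param formula logistic model formula.
#' @param exposure optional exposure name for a pooled PAR.
#' @param boot bootstrap resamples per imputation for the PAR variance.
#' @param seed seed for the PAR bootstrap.
#' @param level confidence level.
#' @return list with `or_table` (term, or, lower, upper, p, and the pooled
#'   log-odds columns) and, when `exposure` is given, `par` (pooled AF with
#'   CI).
#' @export
run_association_suite <- function(imputations, formula, exposure = NULL,
                                  boot = 200, seed = 1, level = 0.95) {
  m <- length(imputations)
  if (m < 1) stop_pedcvh("no imputed datasets supplied")
  fits <- vector("list", m)
  for (i in seq_len(m)) {
    fits[[i]] <- tryCatch(fit_logistic(formula, imputations[[i]], level),
                          error = function(e) {
      stop_pedcvh("logistic fit failed on imputation %d: %s",
                  i, conditionMessage(e))
    })
  }
  est <- do.call(rbind, lapply(fits, function(f) f$table$estimate))
  var <- do.call(rbind, lapply(fits, function(f) f$table$se^2))
  colnames(est) <- colnames(var) <- fits[[1]]$table$term
  pooled <- if (m >= 2) pool_rubin(est, var, level) else {
    f <- fits[[1]]$table
    data.frame(term = f$term, estimate = f$estimate, within = f$se^2,
               between = 0, total = f$se^2, df = Inf,
               lower = log(f$lower), upper = log(f$upper), p = f$p)
  }
  or_table <- data.frame(term = pooled$term, or = exp(pooled$estimate),
                         lower = exp(pooled$lower), upper = exp(pooled$upper),
                         p = pooled$p, log_or = pooled$estimate,
                         se = sqrt(pooled$total))
  out <- list(or_table = or_table, pooled = pooled, m = m)
  if (!is.null(exposure)) {
    afs <- numeric(m); afv <- numeric(m)
    for (i in seq_len(m)) {
      pr <- par_standardized(formula, imputations[[i]], exposure,
                             boot = boot, seed = seed + i, level = level)
      afs[i] <- pr$af
      afv[i] <- if (boot > 0) ((pr$upper - pr$lower) /
                                 (2 * stats::qnorm(1 - (1 - level) / 2)))^2
                else NA_real_
    }
    out$par <- if (m >= 2 && boot > 0) {
      p <- pool_rubin(afs, afv, level)
      list(af = p$estimate, lower = p$lower, upper = p$upper, m = m,
           kind = "model_standardization")
    } else {
      list(af = mean(afs), lower = NA_real_, upper = NA_real_, m = m,
           kind = "model_standardization")
    }
  }
  out
}
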