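# Multiple imputation by chained equations, with Rubin's-rules pooling.
#
# Conditional models by variable type: continuous -> Bayesian linear
# regression (scaled inverse-chi-squared draw of the residual variance and
# a normal draw of the coefficients, then normal or predictive-mean-matching
# draws for the missing cells); binary -> logistic with an approximate
# posterior draw of the coefficients; categorical -> multinomial likewise.
# Parameter perturbation is what keeps between-imputation variance positive;
# deterministic regression imputation would collapse it.

default_mi_method <- function(x) {
  if (is.numeric(x)) "norm"
  else if (is.logical(x) || (is.factor(x) && nlevels(x) == 2)) "logreg"
  else if (is.factor(x) || is.character(x)) "polyreg"
  else stop_pedcvh("no default imputation method for class %s", class(x)[1])
}

# design matrix of the predictors, with aliased columns dropped
mi_design <- function(data, exclude) {
  X <- stats::model.matrix(~ ., data = data[setdiff(names(data), exclude)])
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

draw_beta <- function(coef, vc) {
  ok <- !is.na(coef)
  b <- coef
  ch <- tryCatch(chol(vc[ok, ok, drop = FALSE]), error = function(e) NULL)
  if (!is.null(ch)) {
    b[ok] <- coef[ok] + drop(t(ch) %*% stats::rnorm(sum(ok)))
  }
  b[!ok] <- 0
  b
}

impute_one <- function(y, X, mis, method, pmm_k = 5) {
  obs <- !mis
  Xo <- X[obs, , drop = FALSE]
  Xm <- X[mis, , drop = FALSE]
  if (method %in% c("norm", "pmm")) {
    fit <- stats::lm.fit(Xo, y[obs])
    keep <- !is.na(fit$coefficients)
    Xo2 <- Xo[, keep, drop = FALSE]; Xm2 <- Xm[, keep, drop = FALSE]
    bhat <- fit$coefficients[keep]
    res <- y[obs] - drop(Xo2 %*% bhat)
    df <- max(length(res) - length(bhat), 1)
    sig2 <- sum(res^2) / stats::rchisq(1, df)
    XtXi <- chol2inv(chol(crossprod(Xo2) + diag(1e-8, ncol(Xo2))))
    bstar <- bhat + drop(t(chol(sig2 * XtXi)) %*% stats::rnorm(length(bhat)))
    mu <- drop(Xm2 %*% bstar)
    if (method == "norm") {
      mu + stats::rnorm(length(mu), 0, sqrt(sig2))
    } else {
      mu_obs <- drop(Xo2 %*% bstar)
      vapply(mu, function(m) {
        don <- order(abs(mu_obs - m))[seq_len(min(pmm_k, length(mu_obs)))]
        y[obs][sample(don, 1)]
      }, numeric(1))
    }
  } else if (method == "logreg") {
    yf <- if (is.logical(y)) y else y == levels(y)[2]
    fit <- suppressWarnings(stats::glm.fit(Xo, yf[obs],
                                           family = stats::binomial()))
    vc <- chol2inv(chol(crossprod(Xo * sqrt(fit$weights)) + diag(1e-8, ncol(Xo))))
    bstar <- draw_beta(fit$coefficients, vc)
    p <- stats::plogis(drop(Xm %*% bstar))
    draw <- stats::runif(length(p)) < p
    if (is.logical(y)) draw else factor(levels(y)[draw + 1L], levels = levels(y))
  } else if (method == "polyreg") {
    dfr <- data.frame(.y = y[obs], X = I(Xo[, -1, drop = FALSE]))
    fit <- nnet::multinom(.y ~ X, data = dfr, trace = FALSE, maxit = 200,
                          Hess = TRUE)
    co <- stats::coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1)
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    bvec <- as.numeric(t(co))
    if (!is.null(vc) && nrow(vc) == length(bvec)) {
      bvec <- draw_beta(bvec, vc)
    }
    B <- matrix(bvec, nrow = nrow(co), byrow = TRUE)
    eta <- cbind(0, Xm %*% t(B))
    pr <- exp(eta - apply(eta, 1, max))
    pr <- pr / rowSums(pr)
    idx <- apply(pr, 1, function(p) sample.int(length(p), 1, prob = p))
    factor(levels(y)[idx], levels = levels(y))
  } else {
    stop_pedcvh("unknown imputation method '%s'", method)
  }
}

#' Multiple imputation by chained equations
#'
#' Fills missing values in `data` m times.  Variables with no missing
#' values act as predictors only.  Each of the m datasets is produced by
#' `maxit` sweeps over the incomplete variables (in order of increasing
#' missingness), refitting the conditional model of each variable on all
#' others and drawing imputations with parameter perturbation.
#'
#' @param data data frame; observed values are never modified.
#' @param m number of imputed datasets (default 30).
#' @param maxit chained iterations per dataset (default 10).
#' @param seed integer seed; imputations are reproducible given it.
#' @param method optional named character vector overriding the per-variable
#'   default ("norm", "pmm", "logreg", "polyreg").
#' @param verbose log chain means of imputed continuous variables.
#' @return object of class `mi_result`: list with `imputations` (list of m
#'   complete data frames), `m`, `maxit`, `seed`, `chain_means`.
#' @export
impute_chained <- function(data, m = 30, maxit = 10, seed = 1,
                           method = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(data))
  if (m < 2) stop_pedcvh("impute_chained: m must be >= 2")
  if (maxit < 1) stop_pedcvh("impute_chained: maxit must be >= 1")
  data <- as.data.frame(data)
  chr <- vapply(data, is.character, logical(1)) & names(data) != "id"
  for (v in names(data)[chr]) data[[v]] <- factor(data[[v]])

  nmis <- vapply(data, function(x) sum(is.na(x)), integer(1))
  if (any(nmis == nrow(data))) {
    stop_pedcvh("variable '%s' is entirely missing; conditional model inestimable",
                names(data)[nmis == nrow(data)][1])
  }
  targets <- names(nmis)[nmis > 0]
  set.seed(seed)
  if (!length(targets)) {
    return(structure(list(imputations = rep(list(data), m), m = m,
                          maxit = maxit, seed = seed, chain_means = NULL),
                     class = "mi_result"))
  }
  targets <- targets[order(nmis[targets])]
  methods <- vapply(targets, function(v) {
    (method %||% character())[v] %||% NA_character_
  }, character(1))
  methods[is.na(methods)] <- vapply(data[targets][is.na(methods)],
                                    default_mi_method, character(1))
  mis_idx <- lapply(data[targets], function(x) is.na(x))

  chain_means <- array(NA_real_, c(m, maxit, length(targets)),
                       dimnames = list(NULL, NULL, targets))
  imputations <- vector("list", m)
  for (d in seq_len(m)) {
    cur <- data
    for (v in targets) {           # initialize from observed margins
      cur[[v]][mis_idx[[v]]] <- sample(data[[v]][!is.na(data[[v]])],
                                       sum(mis_idx[[v]]), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in targets) {
        X <- mi_design(cur, exclude = c(v, "id"))
        cur[[v]][mis_idx[[v]]] <- impute_one(data[[v]], X, mis_idx[[v]],
                                             methods[[v]])[
          order(which(mis_idx[[v]]))]
        if (is.numeric(cur[[v]])) {
          chain_means[d, it, v] <- mean(cur[[v]][mis_idx[[v]]])
        }
      }
    }
    imputations[[d]] <- cur
    if (verbose) message("imputed dataset ", d, "/", m)
  }
  structure(list(imputations = imputations, m = m, maxit = maxit,
                 seed = seed, chain_means = chain_means),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat("<mi_result>", x$m, "imputed datasets,", x$maxit, "iterations\n")
  invisible(x)
}

#' Rubin's rules pooling
#'
#' Combines m per-imputation estimates and variances: pooled estimate
#' Qbar = mean(Q); between-imputation variance B = var(Q); total variance
#' T = Wbar + (1 + 1/m) B; small-sample degrees of freedom
#' nu = (m - 1) (1 + Wbar / ((1 + 1/m) B))^2; CI from the t distribution.
#'
#' @param estimates numeric vector (length m) or m x p matrix of estimates.
#' @param variances matching vector/matrix of squared standard errors.
#' @param level confidence level.
#' @return data frame with estimate, within, between, total, df, lower,
#'   upper, p (two-sided test of zero).
#' @export
pool_rubin <- function(estimates, variances, level = 0.95) {
  if (is.vector(estimates)) estimates <- matrix(estimates, ncol = 1)
  if (is.vector(variances)) variances <- matrix(variances, ncol = 1)
  if (!all(dim(estimates) == dim(variances))) {
    stop_pedcvh("pool_rubin: estimates and variances must have matching shape")
  }
  m <- nrow(estimates)
  if (m < 2) stop_pedcvh("pool_rubin: need m >= 2 imputations")
  qbar <- colMeans(estimates)
  wbar <- colMeans(variances)
  b <- apply(estimates, 2, stats::var)
  tot <- wbar + (1 + 1 / m) * b
  df <- ifelse(b > 0, (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2, Inf)
  se <- sqrt(tot)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  out <- data.frame(
    term = colnames(estimates) %||% paste0("q", seq_along(qbar)),
    estimate = qbar, within = wbar, between = b, total = tot, df = df,
    lower = qbar - tq * se, upper = qbar + tq * se,
    p = 2 * stats::pt(-abs(qbar / se), df)
  )
  rownames(out) <- NULL
  out
}
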