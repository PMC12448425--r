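# Multivariable models: Huber-weight robust linear regression for the
# continuous EOR outcome and maximum-likelihood logistic regression for the
# binary focal-deficit outcome. Both are iteratively (re)weighted least
# squares implemented here; MASS::rlm and stats::glm act as oracles in the
# test suite.

#' Specify a multivariable model
#'
#' The EOR models adjust the shape predictor for age, preoperative volume,
#' eloquence and lobar location; the deficit models adjust for age,
#' preoperative volume and eloquence (no location, matching the published
#' model structure).
#'
#' @param outcome `"eor"` or `"focal_deficit"`.
#' @param shape_predictor `"csa"` or `"si"`.
#' @param location_reference Reference category for the lobar-location
#'   dummies (default `"central_deep"`, the category absent from the
#'   published coefficient rows).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("eor", "focal_deficit"),
                       shape_predictor = c("csa", "si"),
                       location_reference = "central_deep") {
  outcome <- match.arg(outcome)
  shape_predictor <- match.arg(shape_predictor)
  if (!location_reference %in% LOCATION_LEVELS) {
    ts_validation_error(sprintf("'location_reference' must be one of: %s",
                                paste(LOCATION_LEVELS, collapse = ", ")))
  }
  covariates <- if (outcome == "eor") {
    c("age", "pre_volume_cm3", "eloquent", "location")
  } else {
    c("age", "pre_volume_cm3", "eloquent")
  }
  structure(list(outcome = outcome, shape_predictor = shape_predictor,
                 covariates = covariates,
                 location_reference = location_reference),
            class = "model_spec")
}

# Build (X, y, n_dropped) from a cohort for a model_spec. Biopsy-only rows
# and incomplete cases are excluded (complete-case per model).
build_design <- function(spec, cohort) {
  cohort <- validate_cohort(cohort)
  shape_col <- if (spec$shape_predictor == "csa") "csa_cm2" else "si"
  outcome_col <- if (spec$outcome == "eor") "eor" else "focal_deficit"
  cols <- c(outcome_col, shape_col, spec$covariates)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    ts_validation_error(sprintf("cohort is missing model column(s): %s",
                                paste(missing_cols, collapse = ", ")))
  }
  dat <- cohort[!cohort$biopsy_only, cols, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) == 0L) {
    ts_stats_error(sprintf(
      "no analyzable rows for outcome '%s' (all biopsy-only or incomplete)",
      spec$outcome))
  }
  y <- if (outcome_col == "focal_deficit") as.numeric(dat[[outcome_col]]) else dat[[outcome_col]]
  X <- cbind(1, dat[[shape_col]], dat$age, dat$pre_volume_cm3,
             as.numeric(dat$eloquent))
  colnames(X) <- c("(Intercept)", toupper(spec$shape_predictor), "age",
                   "pre_volume_cm3", "eloquent")
  if ("location" %in% spec$covariates) {
    loc <- factor(dat$location,
                  levels = c(spec$location_reference,
                             setdiff(LOCATION_LEVELS, spec$location_reference)))
    loc <- droplevels(loc)
    if (nlevels(loc) > 1L) {
      mm <- stats::model.matrix(~loc)[, -1, drop = FALSE]
      colnames(mm) <- sub("^loc", "location:", colnames(mm))
      X <- cbind(X, mm)
    }
  }
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    ts_stats_error(sprintf("design matrix is rank deficient; aliased column(s): %s",
                           paste(aliased, collapse = ", ")))
  }
  list(X = X, y = y, n = nrow(X))
}

regression_fit <- function(model, coefficients, converged, iterations, n,
                           scale = NA_real_, extra = list()) {
  structure(c(list(model = model, coefficients = coefficients,
                   converged = converged, iterations = iterations,
                   n = n, scale = scale), extra),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<%s fit> n = %d, %s after %d iterations\n", x$model, x$n,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cf <- x$coefficients
  cf_fmt <- data.frame(
    term = cf$term,
    `coefficient (95% CI)` = sprintf("%.4g (%.4g, %.4g)", cf$estimate,
                                     cf$ci_lower, cf$ci_upper),
    `p value` = signif(cf$p_value, 3), check.names = FALSE)
  print(cf_fmt, row.names = FALSE)
  invisible(x)
}

#' Huber-weight robust linear regression (IRLS workhorse)
#'
#' Iteratively reweighted least squares with Huber weights
#' `w = min(1, k * s / |r|)` where the scale `s` is the normalized median
#' absolute residual (`median(|r|) / 0.6745`), re-estimated each iteration.
#' Convergence when the largest coefficient change drops below `tol`.
#' Standard errors use the standard M-estimation asymptotic covariance with
#' Huber's small-sample correction; confidence intervals and p-values are
#' normal-theory.
#'
#' @param X Design matrix including the intercept column.
#' @param y Response vector.
#' @param k Huber tuning constant (1.345 gives 95% Gaussian efficiency).
#' @param tol Convergence tolerance on coefficient changes.
#' @param max_iter Iteration cap.
#' @return A `regression_fit`.
#' @export
huber_irls <- function(X, y, k = 1.345, tol = 1e-8, max_iter = 200L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) ts_stats_error("'X' and 'y' sizes disagree")
  if (n <= p) ts_stats_error("more parameters than observations")
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    ts_stats_error(sprintf("design matrix is rank deficient; aliased column(s): %s",
                           paste(aliased, collapse = ", ")))
  }
  beta <- qr.coef(qrX, y)
  converged <- FALSE
  iter <- 0L
  s <- stats::median(abs(y - X %*% beta)) / 0.6745
  last_change <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- as.vector(y - X %*% beta)
    s <- stats::median(abs(r)) / 0.6745
    if (s <= 0) { # exact fit: weights irrelevant from here on
      converged <- TRUE
      break
    }
    w <- pmin(1, k * s / abs(r))
    w[!is.finite(w)] <- 1
    fit <- stats::lm.wfit(X, y, w)
    change <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    last_change <- change
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    ts_stats_error(sprintf(
      "Huber IRLS did not converge in %d iterations (last change %.3g)",
      max_iter, last_change))
  }
  r <- as.vector(y - X %*% beta)
  if (s <= 0) {
    se <- rep(0, p)
  } else {
    psi <- pmax(-k * s, pmin(k * s, r))
    dpsi <- as.numeric(abs(r) <= k * s)
    m1 <- mean(dpsi)
    kappa <- 1 + p / n * stats::var(dpsi) / m1^2   # Huber's correction
    v <- kappa^2 * (sum(psi^2) / (n - p)) / m1^2
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(v * diag(XtXinv))
  }
  z <- stats::qnorm(0.975)
  cf <- data.frame(term = colnames(X), estimate = unname(beta), se = se,
                   ci_lower = unname(beta) - z * se,
                   ci_upper = unname(beta) + z * se,
                   p_value = 2 * stats::pnorm(-abs(unname(beta) / ifelse(se > 0, se, Inf))),
                   stringsAsFactors = FALSE)
  regression_fit("huber", cf, converged, iter, n, scale = s)
}

#' Logistic regression by Newton-Raphson IRLS
#'
#' Maximum-likelihood fit with step-halving (the log-likelihood never
#' decreases across accepted iterations), Wald 95% confidence intervals and
#' p-values. Complete or quasi-complete separation is detected (diverging
#' linear predictor) and raised as an explicit error rather than silent
#' output.
#'
#' @param X Design matrix including the intercept column.
#' @param y Binary response (0/1 or logical); both classes must be present.
#' @param tol Convergence tolerance on coefficient changes.
#' @param max_iter Iteration cap.
#' @return A `regression_fit` with the iteration log-likelihood trace in
#'   `$loglik_trace`.
#' @export
logistic_irls <- function(X, y, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) ts_stats_error("'X' and 'y' sizes disagree")
  if (!all(y %in% c(0, 1))) ts_stats_error("outcome must be binary (0/1)")
  if (length(unique(y)) < 2L) {
    ts_stats_error("outcome has a single class; logistic model is undefined")
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    ts_stats_error(sprintf("design matrix is rank deficient; aliased column(s): %s",
                           paste(aliased, collapse = ", ")))
  }
  # numerically stable log(1 + exp(eta))
  log1pexp <- function(eta) ifelse(eta > 0, eta + log1p(exp(-eta)),
                                   log1p(exp(eta)))
  loglik <- function(eta) sum(y * eta - log1pexp(eta))
  beta <- rep(0, p)
  eta <- as.vector(X %*% beta)
  ll <- loglik(eta)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    # step-halving keeps the log-likelihood non-decreasing
    step <- 1
    repeat {
      cand <- beta + step * (new_beta - beta)
      eta_c <- as.vector(X %*% cand)
      ll_c <- loglik(eta_c)
      if (ll_c >= ll - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    change <- max(abs(cand - beta))
    beta <- cand; eta <- eta_c; ll <- ll_c
    trace <- c(trace, ll)
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    # separation makes the MLE diverge: the IRLS coefficients grow without
    # bound and the fitted probabilities pin to their classes. A genuinely
    # hard but well-posed fit just needs more iterations.
    mu <- stats::plogis(eta)
    pinned <- all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6)
    if (pinned || max(abs(eta)) > 30) {
      ts_stats_error(paste0(
        "complete or quasi-complete separation detected ",
        "(diverging linear predictor); coefficients are unbounded"))
    }
    ts_stats_error(sprintf("logistic IRLS did not converge in %d iterations",
                           max_iter))
  }
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e)
    ts_stats_error("information matrix is singular"))
  se <- sqrt(diag(cov))
  zq <- stats::qnorm(0.975)
  cf <- data.frame(term = colnames(X), estimate = unname(beta), se = se,
                   ci_lower = unname(beta) - zq * se,
                   ci_upper = unname(beta) + zq * se,
                   p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
                   stringsAsFactors = FALSE)
  regression_fit("logistic", cf, converged, iter, n,
                 extra = list(loglik = ll, loglik_trace = trace))
}

#' Fit the robust EOR model declared by a model spec
#'
#' @param spec A [model_spec()] with outcome `"eor"`.
#' @param cohort Cohort data.frame; biopsy-only and incomplete rows are
#'   excluded.
#' @param k,tol,max_iter Passed to [huber_irls()].
#' @return A `regression_fit`.
#' @export
huber_fit <- function(spec, cohort, k = 1.345, tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$outcome != "eor") {
    ts_validation_error("huber_fit expects a continuous-outcome (eor) model spec")
  }
  d <- build_design(spec, cohort)
  huber_irls(d$X, d$y, k = k, tol = tol, max_iter = max_iter)
}

#' Fit the logistic focal-deficit model declared by a model spec
#'
#' @param spec A [model_spec()] with outcome `"focal_deficit"`.
#' @param cohort Cohort data.frame; biopsy-only and incomplete rows are
#'   excluded.
#' @param tol,max_iter Passed to [logistic_irls()].
#' @return A `regression_fit`.
#' @export
logistic_fit <- function(spec, cohort, tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$outcome != "focal_deficit") {
    ts_validation_error("logistic_fit expects a binary-outcome (focal_deficit) model spec")
  }
  d <- build_design(spec, cohort)
  logistic_irls(d$X, d$y, tol = tol, max_iter = max_iter)
}
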