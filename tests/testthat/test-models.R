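# Regression models: identifiability, robustness, oracle agreement,
# separation handling, and the model-spec design contracts.

test_that("huber_irls recovers exact linear data to machine precision", {
  set.seed(1)
  X <- cbind(1, rnorm(50), runif(50))
  beta <- c(2, -1.5, 0.25)
  fit <- huber_irls(X, as.vector(X %*% beta))
  expect_equal(fit$coefficients$estimate, beta, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("huber_irls matches OLS on clean Gaussian data within 1e-3", {
  set.seed(2)
  X <- cbind(1, rnorm(1000))
  y <- as.vector(X %*% c(1, 2)) + rnorm(1000, sd = 0.1)
  hub <- huber_irls(X, y)$coefficients$estimate
  ols <- stats::lm.fit(X, y)$coefficients
  expect_lt(max(abs(hub - ols)), 1e-3)
})

test_that("huber equals OLS exactly in the large-threshold limit", {
  set.seed(3)
  X <- cbind(1, rnorm(100))
  y <- as.vector(X %*% c(0.5, -1)) + rnorm(100)
  hub <- huber_irls(X, y, k = 1e9)$coefficients$estimate
  ols <- stats::lm.fit(X, y)$coefficients
  expect_equal(hub, unname(ols), tolerance = 1e-12)
})

test_that("huber beats OLS under a single gross outlier", {
  set.seed(4)
  X <- cbind(1, rnorm(100))
  sigma <- 0.5
  y <- as.vector(X %*% c(1, 2)) + rnorm(100, sd = sigma)
  y[7] <- y[7] + 100 * sigma
  hub <- huber_irls(X, y)$coefficients$estimate[2]
  ols <- stats::lm.fit(X, y)$coefficients[2]
  expect_lt(abs(hub - 2), abs(ols - 2))
})

test_that("huber_irls agrees with the MASS::rlm oracle", {
  set.seed(5)
  x1 <- rnorm(150); x2 <- runif(150)
  y <- 1 + 0.8 * x1 - 2 * x2 + rt(150, df = 3)
  X <- cbind(1, x1, x2)
  ours <- huber_irls(X, y)
  ref <- MASS::rlm(y ~ x1 + x2, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 200, acc = 1e-8)
  expect_equal(ours$coefficients$estimate, unname(coef(ref)), tolerance = 1e-5)
  expect_equal(ours$coefficients$se, unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 0.05)
  expect_equal(ours$scale, unname(ref$s), tolerance = 1e-3)
})

test_that("huber CIs bracket the estimate and flag rank deficiency", {
  set.seed(6)
  X <- cbind(1, rnorm(40))
  y <- rnorm(40)
  fit <- huber_irls(X, y)
  cf <- fit$coefficients
  expect_true(all(cf$ci_lower <= cf$estimate & cf$estimate <= cf$ci_upper))
  Xbad <- cbind(X, 2 * X[, 2])
  colnames(Xbad) <- c("a", "b", "twice_b")
  err <- tryCatch(huber_irls(Xbad, y), condition = identity)
  expect_s3_class(err, "tumorshape_stats_error")
  expect_match(conditionMessage(err), "twice_b")
})

test_that("logistic intercept-only fit is the empirical logit", {
  y <- rep(c(0, 1), each = 25)
  fit <- logistic_irls(matrix(1, 50), y)
  expect_equal(fit$coefficients$estimate, 0, tolerance = 1e-10)
  y2 <- c(rep(1, 30), rep(0, 10))
  fit2 <- logistic_irls(matrix(1, 40), y2)
  expect_equal(fit2$coefficients$estimate, stats::qlogis(0.75), tolerance = 1e-8)
})

test_that("logistic 2x2 coefficient equals the log odds ratio ln(4)", {
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  x <- c(rep(1, 30), rep(0, 30))
  fit <- logistic_irls(cbind(1, x), y)
  expect_equal(fit$coefficients$estimate[2], log(4), tolerance = 1e-6)
})

test_that("logistic_irls matches glm and keeps the likelihood monotone", {
  set.seed(8)
  x <- rnorm(200)
  y <- rbinom(200, 1, stats::plogis(-0.4 + 1.1 * x))
  ours <- logistic_irls(cbind(1, x), y)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(ours$coefficients$estimate, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(ours$coefficients$se,
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-3)
  expect_true(all(diff(ours$loglik_trace) >= -1e-9))
})

test_that("separation and degenerate outcomes raise explicit errors", {
  x <- c(rnorm(20, -2), rnorm(20, 2))
  y <- as.numeric(x > 0)
  expect_error(logistic_irls(cbind(1, x), y), "separation",
               class = "tumorshape_stats_error")
  expect_error(logistic_irls(cbind(1, x), rep(1, 40)),
               class = "tumorshape_stats_error")
  expect_error(logistic_irls(cbind(1, x), c(0.5, rep(0, 39))),
               class = "tumorshape_stats_error")
})

test_that("model fits honor the spec contracts on a simulated cohort", {
  co <- simulate_cohort(cohort_spec(n_patients = 800, seed = 14))
  fit <- huber_fit(model_spec("eor", "csa"), co)
  terms <- fit$coefficients$term
  expect_true(all(c("(Intercept)", "CSA", "age", "pre_volume_cm3",
                    "eloquent") %in% terms))
  expect_true(any(grepl("^location:", terms)))
  expect_false(any(grepl("central_deep", terms)))  # reference level
  expect_equal(fit$n, sum(!co$biopsy_only))
  # deficit models carry no location dummies
  dfit <- logistic_fit(model_spec("focal_deficit", "si"), co)
  expect_false(any(grepl("^location:", dfit$coefficients$term)))

  co2 <- co; co2$location <- NULL
  expect_error(huber_fit(model_spec("eor", "csa"), co2), "location",
               class = "tumorshape_validation_error")
  expect_error(huber_fit(model_spec("focal_deficit", "csa"), co),
               class = "tumorshape_validation_error")
})

test_that("injected effect signs are recovered at n = 5000", {
  co <- simulate_cohort(cohort_spec(n_patients = 5000, seed = 15))
  eor_csa <- huber_fit(model_spec("eor", "csa"), co)$coefficients
  expect_lt(eor_csa$estimate[eor_csa$term == "CSA"], 0)
  expect_lt(eor_csa$p_value[eor_csa$term == "CSA"], 0.05)
  eor_si <- huber_fit(model_spec("eor", "si"), co)$coefficients
  expect_lt(eor_si$estimate[eor_si$term == "SI"], 0)
  def_si <- logistic_fit(model_spec("focal_deficit", "si"), co)$coefficients
  expect_gt(def_si$estimate[def_si$term == "SI"], 0)
  expect_lt(def_si$p_value[def_si$term == "SI"], 0.05)
})
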