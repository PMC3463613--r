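test_that("a flat 50% series fits to zero coefficients", {
  sr <- survival_series(c(1, 2, 3), rep(100, 3), rep(50, 3))
  fit <- fit_logistic_survival(sr, model_config(degree = 1))
  expect_true(all(abs(fit$coefficients) < 1e-8))
  expect_true(fit$converged)
})

test_that("a two-point saturated fit reproduces the closed-form logit line", {
  sr <- survival_series(c(10, 20), c(10, 10), c(8, 2))
  fit <- fit_logistic_survival(sr, model_config(degree = 1))
  # line through logit(0.8) = ln 4 at t=10 and logit(0.2) = -ln 4 at t=20
  expect_equal(fit$coefficients[2], -0.27726, tolerance = 1e-4)
  expect_equal(fit$coefficients[1], 4.1589, tolerance = 1e-4)
  expect_equal(fit$fitted, c(0.8, 0.2), tolerance = 1e-8)
  expect_equal(fit$df_residual, 0L)
})

test_that("IRLS matches a brute-force likelihood-grid maximizer on the 4-point series", {
  t <- c(5, 10, 15, 20); n <- rep(20, 4); y <- c(19, 15, 8, 2)
  fit <- fit_logistic_survival(survival_series(t, n, y),
                               model_config(degree = 1))
  oracle <- grid_mle_degree1(t, n, y)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-3)
})

test_that("IRLS agrees with stats::glm on simulated data at both degrees", {
  cv <- survival_curve(c(7.2, -0.55, 0.012, -0.0002), c(2, 34))
  for (deg in c(1L, 3L)) {
    for (seed in c(21, 22)) {
      sr <- simulate_lifespan_series(cv, lifespan_design(seed = seed))
      fit <- fit_logistic_survival(sr, model_config(degree = deg))
      df <- as.data.frame(sr)
      g <- stats::glm(
        cbind(n_alive, n_scored - n_alive) ~
          poly(timepoint_days, deg, raw = TRUE),
        family = stats::binomial, data = df)
      expect_equal(unname(fit$coefficients), unname(stats::coef(g)),
                   tolerance = 1e-6)
      gq <- stats::glm(
        cbind(n_alive, n_scored - n_alive) ~
          poly(timepoint_days, deg, raw = TRUE),
        family = stats::quasibinomial, data = df)
      expect_equal(fit$dispersion_raw, summary(gq)$dispersion,
                   tolerance = 1e-4)
    }
  }
})

test_that("Pearson dispersion matches the hand-computed statistic and floors at 1", {
  t <- c(5, 10, 15, 20); n <- rep(20, 4); y <- c(19, 15, 8, 2)
  sr <- survival_series(t, n, y)
  fit <- fit_logistic_survival(sr, model_config(degree = 1))
  # hand computation with oracle fitted proportions
  p_or <- stats::plogis(grid_mle_degree1(t, n, y)[1] +
                          grid_mle_degree1(t, n, y)[2] * t)
  chi2 <- sum((y - n * p_or)^2 / (n * p_or * (1 - p_or)))
  phi <- pearson_dispersion(fit, sr)
  expect_equal(attr(phi, "raw"), chi2 / 2, tolerance = 1e-6)
  expect_equal(as.numeric(phi), 1)  # floored: raw ~0.034 < 1

  # residual-free fit: collinear empirical logits, one residual df
  perf <- survival_series(c(10, 20, 30), rep(10, 3), c(8, 5, 2))
  pf <- fit_logistic_survival(perf, model_config(degree = 1))
  expect_equal(attr(pearson_dispersion(pf), "raw"), 0,
               tolerance = 1e-12)
  expect_equal(as.numeric(pearson_dispersion(pf)), 1)
})

test_that("doubling the dispersion doubles every covariance entry", {
  sr <- survival_series(c(5, 10, 15, 20), rep(20, 4), c(19, 15, 8, 2))
  f1 <- fit_logistic_survival(sr, model_config(dispersion_floor = 1))
  f2 <- fit_logistic_survival(sr, model_config(dispersion_floor = 2))
  expect_equal(f2$covariance, 2 * f1$covariance, tolerance = 1e-12)
})

test_that("dispersion is undefined for saturated fits", {
  sr <- survival_series(c(10, 20), c(10, 10), c(8, 2))
  fit <- fit_logistic_survival(sr, model_config(degree = 1))
  expect_true(is.na(fit$dispersion_raw))
  expect_error(pearson_dispersion(fit), "saturated")
})

test_that("predict_survival inverts the logit and flags extrapolation", {
  f <- fake_fit(c(4.1589, -0.27726), c(0, 40))
  expect_equal(predict_survival(f, 15), 0.5, tolerance = 1e-4)
  expect_equal(predict_survival(f, 10), 0.8, tolerance = 1e-4)
  f2 <- fake_fit(c(5, -0.25), c(0, 30))
  expect_equal(predict_survival(f2, 40, warn_extrapolation = FALSE),
               stats::plogis(-5), tolerance = 1e-5)
  expect_warning(predict_survival(f2, 40), "outside the data window")
})

test_that("saturated-consistency: interior fits pass through every observed logit", {
  set.seed(31)
  for (i in 1:20) {
    y <- sample(2:8, 2)
    sr <- survival_series(sort(sample(1:30, 2)), c(10, 10), y)
    fit <- fit_logistic_survival(sr, model_config(degree = 1))
    expect_equal(fit$fitted, y / 10, tolerance = 1e-7)
  }
  y4 <- c(17, 12, 9, 4)
  sr4 <- survival_series(c(4, 9, 15, 22), rep(20, 4), y4)
  f4 <- fit_logistic_survival(sr4, model_config(degree = 3))
  expect_equal(f4$fitted, y4 / 20, tolerance = 1e-7)
})

test_that("cubic IRLS matches a multi-start likelihood-surface search", {
  cv <- survival_curve(c(7.2, -0.55, 0.012, -0.0002), c(2, 34))
  sr <- simulate_lifespan_series(
    cv, lifespan_design(timepoints = seq(4, 28, 4), seed = 8))
  fit <- fit_logistic_survival(sr, model_config(degree = 3))
  oracle <- surface_mle(sr$timepoints, sr$n_scored, sr$n_alive, 3L)
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-3)
})

test_that("degenerate and ill-posed inputs are rejected", {
  expect_error(model_config(degree = 2), "1 .*or 3|degree")
  all1 <- survival_series(c(1, 2, 3), rep(10, 3), rep(10, 3))
  expect_error(fit_logistic_survival(all1), "all .* 1|not estimable")
  sep <- survival_series(1:4, rep(20, 4), c(20, 20, 0, 0))
  expect_error(fit_logistic_survival(sep, model_config(degree = 1)),
               "separation")
  two <- survival_series(c(1, 2), c(10, 10), c(8, 2))
  expect_error(fit_logistic_survival(two, model_config(degree = 3)),
               "at least 4 timepoints")
})

test_that("non-convergence is flagged with a warning, not an error", {
  sr <- survival_series(c(5, 10, 15, 20), rep(20, 4), c(19, 15, 8, 2))
  expect_warning(
    fit <- fit_logistic_survival(sr, model_config(max_iterations = 1L)),
    "did not converge")
  expect_false(fit$converged)
})

test_that("parameter recovery: truth within 3 Wald SEs in at least 95% of seeds", {
  beta_true <- c(5, -0.25)
  cv <- survival_curve(beta_true, c(0, 40))
  design_tp <- seq(4, 32, 2)  # 15 timepoints
  hits <- vapply(1:200, function(s) {
    sr <- simulate_lifespan_series(cv, lifespan_design(
      timepoints = design_tp, n_per_timepoint = 1000L, seed = 5000 + s))
    fit <- fit_logistic_survival(sr, model_config(degree = 1))
    se <- sqrt(diag(fit$covariance))
    all(abs(fit$coefficients - beta_true) <= 3 * se)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
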