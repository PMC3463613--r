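#' Configuration of the polynomial-logit survival model
#'
#' The survival proportion at day t is modelled as
#' \eqn{\mathrm{logit}^{-1}(\beta_0 + \beta_1 t + \dots + \beta_d t^d)} with
#' binomial counts and a quasi-binomial dispersion parameter. Only linear
#' (d = 1) and cubic (d = 3) polynomials are supported: linear fits suit
#' unmanipulated survival data, while cubic fits accommodate the early
#' plateau and late tail seen when progeny production is blocked
#' pharmacologically. Other degrees are rejected rather than silently
#' accepted.
#'
#' @param degree Polynomial degree, 1 or 3.
#' @param max_iterations Maximum IRLS iterations (default 100).
#' @param tolerance Convergence threshold on the maximum absolute
#'   coefficient change between iterations (default 1e-8).
#' @param dispersion_floor Minimum dispersion used to scale the coefficient
#'   covariance (default 1): overdispersion may widen intervals but apparent
#'   underdispersion never shrinks them.
#' @return An object of class `model_config`.
#' @export
model_config <- function(degree = 1L, max_iterations = 100L,
                         tolerance = 1e-8, dispersion_floor = 1) {
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 3L)) {
    stop("'degree' must be 1 (linear) or 3 (cubic)", call. = FALSE)
  }
  if (tolerance <= 0) stop("'tolerance' must be > 0", call. = FALSE)
  structure(
    list(degree = degree, max_iterations = as.integer(max_iterations),
         tolerance = tolerance, dispersion_floor = dispersion_floor),
    class = "model_config"
  )
}

# Map coefficients/covariance on the centred-scaled time axis z = (t-m)/s
# back to the raw day scale: beta_raw = A %*% gamma with
# A[j+1, k+1] = choose(k, j) (-m)^(k-j) / s^k for j <= k.
scale_back_matrix <- function(degree, m, s) {
  A <- matrix(0, degree + 1L, degree + 1L)
  for (k in 0:degree) {
    for (j in 0:k) {
      A[j + 1L, k + 1L] <- choose(k, j) * (-m)^(k - j) / s^k
    }
  }
  A
}

# IRLS for the binomial-logit polynomial model. Works on the centred-scaled
# time axis for conditioning; returns everything needed to build the fit
# object. |eta| > 30 at any data point is treated as (quasi-)separation:
# the likelihood is climbing towards a degenerate fit.
irls_fit <- function(t, n, y, degree, max_iterations = 100L,
                     tolerance = 1e-8) {
  m <- mean(t)
  s <- stats::sd(t)
  z <- (t - m) / s
  Z <- outer(z, 0:degree, `^`)

  # empirical-logit start with Haldane correction handles 0 and n counts
  l0 <- stats::qlogis((y + 0.5) / (n + 1))
  gamma <- qr.coef(qr(Z), l0)
  if (anyNA(gamma)) stop("singular design matrix", call. = FALSE)

  converged <- FALSE
  eta <- drop(Z %*% gamma)
  for (iter in seq_len(max_iterations)) {
    p <- stats::plogis(eta)
    v <- p * (1 - p)
    if (any(v < 1e-12) || max(abs(eta)) > 30) {
      stop("separation: fitted logits diverge (|eta| > 30); ",
           "the likelihood has no finite maximizer", call. = FALSE)
    }
    w <- n * v
    zeta <- eta + (y / n - p) / v          # working response
    sw <- sqrt(w)
    fit <- qr(Z * sw)
    if (fit$rank < degree + 1L) {
      stop("singular weighted design in IRLS", call. = FALSE)
    }
    gamma_new <- qr.coef(fit, zeta * sw)
    delta <- max(abs(gamma_new - gamma))
    gamma <- gamma_new
    eta <- drop(Z %*% gamma)
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(eta)) > 30) {
    stop("separation: fitted logits diverge (|eta| > 30); ",
         "the likelihood has no finite maximizer", call. = FALSE)
  }

  p <- stats::plogis(eta)
  w <- n * p * (1 - p)
  info <- crossprod(Z * sqrt(w))           # t(Z) W Z
  cov_scaled_unit <- chol2inv(chol(info))  # inverse information, phi = 1
  A <- scale_back_matrix(degree, m, s)

  pearson <- sum((y - n * p)^2 / (n * p * (1 - p)))
  ll_terms <- ifelse(y > 0, y * log(y / (n * p)), 0) +
    ifelse(y < n, (n - y) * log((n - y) / (n - n * p)), 0)
  list(
    coefficients = drop(A %*% gamma),
    cov_unit = A %*% cov_scaled_unit %*% t(A),
    fitted = p,
    eta = eta,
    pearson_chi2 = pearson,
    deviance = 2 * sum(ll_terms),
    df_residual = length(t) - (degree + 1L),
    converged = converged,
    iterations = iter
  )
}

#' Fit a polynomial-logit survival model with overdispersion
#'
#' Maximum-likelihood fit of the binomial logistic model with design
#' columns (1, t, ..., t^degree) by iteratively reweighted least squares.
#' The time covariate is centred and scaled internally for numerical
#' conditioning; coefficients and their covariance are reported on the raw
#' day scale. The dispersion parameter is the Pearson chi-squared statistic
#' divided by the residual degrees of freedom, floored at
#' `dispersion_floor`, and scales the coefficient covariance so that counts
#' more variable than binomial widen the intervals.
#'
#' @param series A [survival_series()].
#' @param config A [model_config()].
#' @return An object of class `survival_fit` with elements `coefficients`
#'   (raw day scale, lowest order first), `dispersion` (floored),
#'   `dispersion_raw`, `covariance`, `pearson_chi2`, `deviance`,
#'   `df_residual`, `fitted` (per-timepoint survival proportions),
#'   `converged`, `data_window`, `treatment` and `config`.
#' @examples
#' sr <- survival_series(c(10, 20), c(10, 10), c(8, 2))
#' fit <- fit_logistic_survival(sr, model_config(degree = 1))
#' fit$coefficients  # saturated fit through logit(0.8), logit(0.2)
#' @export
fit_logistic_survival <- function(series, config = model_config()) {
  stopifnot(inherits(series, "survival_series"),
            inherits(config, "model_config"))
  k <- length(series$timepoints)
  if (k < config$degree + 1L) {
    stop("need at least ", config$degree + 1L, " timepoints for degree ",
         config$degree, call. = FALSE)
  }
  if (all(series$n_alive == 0L) || all(series$n_alive == series$n_scored)) {
    stop("all proportions are 0 or all are 1; the logit is not estimable",
         call. = FALSE)
  }

  res <- irls_fit(series$timepoints, series$n_scored, series$n_alive,
                  config$degree, config$max_iterations, config$tolerance)
  if (!res$converged) {
    warning("IRLS did not converge in ", config$max_iterations,
            " iterations", call. = FALSE)
  }

  phi_raw <- if (res$df_residual > 0L) {
    res$pearson_chi2 / res$df_residual
  } else {
    NA_real_
  }
  phi <- max(phi_raw, config$dispersion_floor, na.rm = TRUE)

  structure(
    list(
      coefficients = res$coefficients,
      dispersion = phi,
      dispersion_raw = phi_raw,
      covariance = res$cov_unit * phi,
      pearson_chi2 = res$pearson_chi2,
      deviance = res$deviance,
      df_residual = res$df_residual,
      fitted = res$fitted,
      converged = res$converged,
      iterations = res$iterations,
      data_window = range(series$timepoints),
      treatment = series$treatment,
      config = config
    ),
    class = "survival_fit"
  )
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Polynomial-logit survival fit (degree ", x$config$degree, ", arm '",
      x$treatment, "')\n", sep = "")
  se <- sqrt(diag(x$covariance))
  tab <- data.frame(
    estimate = x$coefficients,
    std.error = se,
    row.names = paste0("beta", seq_along(x$coefficients) - 1L)
  )
  print(signif(tab, 5))
  cat("dispersion (Pearson chi2/df):",
      if (is.na(x$dispersion_raw)) "undefined (saturated)" else
        format(signif(x$dispersion_raw, 5)),
      "-> used:", format(signif(x$dispersion, 5)), "\n")
  cat("deviance:", format(signif(x$deviance, 5)), "on", x$df_residual,
      "df;", if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Predicted survival proportion at given times
#'
#' Evaluates the fitted curve, inverse-logit of the fitted polynomial, at
#' arbitrary times. Extrapolation outside the window of the data the model
#' was fitted to is permitted but flagged with a warning.
#'
#' @param model A `survival_fit`.
#' @param t Numeric vector of times in days.
#' @param warn_extrapolation Warn when any `t` falls outside the data
#'   window (default TRUE).
#' @return Numeric vector of survival proportions in (0, 1).
#' @export
predict_survival <- function(model, t, warn_extrapolation = TRUE) {
  stopifnot(inherits(model, "survival_fit"))
  if (warn_extrapolation &&
      any(t < model$data_window[1] | t > model$data_window[2])) {
    warning("predicting outside the data window [", model$data_window[1],
            ", ", model$data_window[2], "] days", call. = FALSE)
  }
  stats::plogis(eval_logit_poly(model$coefficients, t))
}

#' Pearson overdispersion of a fitted survival model
#'
#' The quasi-binomial moment estimator: the Pearson chi-squared statistic
#' of the fit divided by its residual degrees of freedom, floored at the
#' model's `dispersion_floor`. The raw (unfloored) estimate is attached as
#' attribute `"raw"`.
#'
#' @param model A `survival_fit`.
#' @param series The [survival_series()] the model was fitted to; defaults
#'   to recomputing from the statistics stored in the model.
#' @return The reported (floored) dispersion, with attribute `"raw"`.
#' @export
pearson_dispersion <- function(model, series = NULL) {
  stopifnot(inherits(model, "survival_fit"))
  if (model$df_residual < 1L) {
    stop("dispersion undefined for saturated fit", call. = FALSE)
  }
  chi2 <- if (is.null(series)) {
    model$pearson_chi2
  } else {
    p <- model$fitted
    sum((series$n_alive - series$n_scored * p)^2 /
          (series$n_scored * p * (1 - p)))
  }
  raw <- chi2 / model$df_residual
  structure(max(raw, model$config$dispersion_floor), raw = raw)
}
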