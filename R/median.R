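#' Median lifespan from a fitted survival curve
#'
#' Inverts the fitted polynomial-logit curve at 50% survival: the median is
#' the time where the fitted logit crosses zero going positive to negative
#' (survival falling through 50%). The search window is the data window
#' widened by 25% of its width on each side, scanned on a dense grid and
#' refined by bisection to 1e-9 days. With a cubic polynomial more than one
#' descending crossing is possible; that is reported as an error listing
#' the candidates so the caller can narrow the window.
#'
#' @param model A `survival_fit`.
#' @param window Optional length-2 numeric search window in days; defaults
#'   to the widened data window.
#' @param n_grid Grid points for the sign-change scan (default 2001).
#' @return The estimated median lifespan in days.
#' @examples
#' sr <- survival_series(c(10, 20), c(10, 10), c(8, 2))
#' fit <- fit_logistic_survival(sr, model_config(degree = 1))
#' estimate_median(fit)  # 15: midpoint by symmetry of 0.8 and 0.2
#' @export
estimate_median <- function(model, window = NULL, n_grid = 2001L) {
  stopifnot(inherits(model, "survival_fit"))
  if (is.null(window)) {
    width <- diff(model$data_window)
    window <- model$data_window + c(-0.25, 0.25) * width
  }
  tryCatch(
    descending_root(model$coefficients, window, n_grid = n_grid),
    error = function(e) {
      if (grepl("never reaches", conditionMessage(e))) {
        stop("median not reached within window [", signif(window[1], 6),
             ", ", signif(window[2], 6), "] days", call. = FALSE)
      }
      stop(e)
    }
  )
}

#' Percentile-bootstrap confidence interval for median lifespan
#'
#' Parametric bootstrap of the whole estimation pipeline: for each of B
#' resamples the number alive at every timepoint is redrawn from a binomial
#' distribution with the observed (by default) proportion surviving at that
#' time, the model is refitted, and the median recomputed. The 2.5th and
#' 97.5th percentiles of the retained bootstrap medians (linear
#' interpolation between order statistics, [stats::quantile()] type 7) form
#' the 95% interval. Resamples whose fit fails or whose median is undefined
#' are excluded and counted; more than 5% of failures aborts with advice to
#' widen the window or lower the degree.
#'
#' @param series A [survival_series()].
#' @param config A [model_config()].
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer RNG seed (required; same seed, same interval).
#' @param resample `"observed"` (default) resamples at the observed
#'   proportions; `"fitted"` at the model's fitted proportions.
#' @param resample_rho Beta-binomial intra-class correlation used when
#'   resampling (default 0 = plain binomial, matching the estimator's
#'   binomial working model).
#' @param level Confidence level (default 0.95).
#' @return An object of class `median_estimate` with elements `point`,
#'   `ci_low`, `ci_high`, `n_bootstrap`, `n_failed_resamples`, `seed`,
#'   `level` and the retained `boot_medians`.
#' @export
bootstrap_median_ci <- function(series, config = model_config(), B = 1000L,
                                seed,
                                resample = c("observed", "fitted"),
                                resample_rho = 0, level = 0.95) {
  stopifnot(inherits(series, "survival_series"),
            inherits(config, "model_config"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  B <- as.integer(B)
  if (B < 2L) stop("'B' must be >= 2", call. = FALSE)
  resample <- match.arg(resample)

  fit <- fit_logistic_survival(series, config)
  point <- estimate_median(fit)

  t <- series$timepoints
  n <- series$n_scored
  k <- length(t)
  p_hat <- if (resample == "observed") series$n_alive / n else fit$fitted
  width <- diff(fit$data_window)
  window <- fit$data_window + c(-0.25, 0.25) * width

  boot <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      p_b <- if (resample_rho > 0) {
        conc <- (1 - resample_rho) / resample_rho
        stats::rbeta(k, p_hat * conc, (1 - p_hat) * conc)
      } else {
        p_hat
      }
      y_b <- stats::rbinom(k, n, p_b)
      tryCatch({
        if (all(y_b == 0L) || all(y_b == n)) stop("degenerate resample")
        r <- irls_fit(t, n, y_b, config$degree, config$max_iterations,
                      config$tolerance)
        descending_root(r$coefficients, window, n_grid = 2001L)
      }, error = function(e) NA_real_)
    }, numeric(1))
  })

  n_failed <- sum(is.na(boot))
  if (n_failed > 0.05 * B) {
    stop(n_failed, "/", B, " bootstrap resamples failed to yield a median; ",
         "widen the window or lower the polynomial degree", call. = FALSE)
  }
  kept <- boot[!is.na(boot)]
  alpha <- round((1 - level) / 2, 10)  # 0.95 -> exactly 0.025 / 0.975
  ci <- unname(stats::quantile(kept, c(alpha, 1 - alpha), type = 7))

  structure(
    list(point = point, ci_low = ci[1], ci_high = ci[2],
         n_bootstrap = B, n_failed_resamples = n_failed,
         seed = as.integer(seed), level = level, boot_medians = kept,
         treatment = series$treatment, config = config),
    class = "median_estimate"
  )
}

#' @export
print.median_estimate <- function(x, ...) {
  cat("Median lifespan (arm '", x$treatment, "'): ",
      format(signif(x$point, 4)), " days\n", sep = "")
  cat(format(100 * x$level), "% percentile-bootstrap CI: (",
      format(signif(x$ci_low, 4)), ", ", format(signif(x$ci_high, 4)),
      ") days  [B = ", x$n_bootstrap, ", ", x$n_failed_resamples,
      " failed]\n", sep = "")
  invisible(x)
}

#' Empirical coverage of the bootstrap median interval
#'
#' Simulation harness validating the nominal confidence level: simulates
#' `reps` independent count series from a known curve, computes the
#' percentile-bootstrap interval for each, and reports the fraction of
#' intervals containing the generating curve's true median.
#'
#' @param curve A [survival_curve()] whose median is reachable in its
#'   window.
#' @param design A [lifespan_design()] (its own seed is ignored; per-rep
#'   seeds derive from `seed`).
#' @param reps Number of replicate datasets.
#' @param B Bootstrap resamples per dataset.
#' @param config A [model_config()].
#' @param seed Integer master seed.
#' @return An object of class `coverage_result`: `coverage` (fraction in
#'   \[0, 1\]), `true_median`, `n_failed_reps` and a per-rep data frame
#'   `log` with columns `rep`, `point`, `ci_low`, `ci_high`, `covered`,
#'   `failed`.
#' @export
coverage_experiment <- function(curve, design, reps = 200L, B = 300L,
                                config = model_config(degree = 3L), seed) {
  stopifnot(inherits(curve, "survival_curve"),
            inherits(design, "lifespan_design"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  target <- true_median(curve)

  seeds <- withr::with_seed(seed,
                            matrix(sample.int(2147483646L, 2L * reps), ncol = 2L))
  rows <- vector("list", reps)
  for (i in seq_len(reps)) {
    rows[[i]] <- tryCatch({
      d_i <- lifespan_design(design$timepoints, design$n_per_timepoint,
                             design$overdispersion_rho, seed = seeds[i, 1L])
      sr <- simulate_lifespan_series(curve, d_i)
      est <- bootstrap_median_ci(sr, config, B = B, seed = seeds[i, 2L])
      data.frame(rep = i, point = est$point, ci_low = est$ci_low,
                 ci_high = est$ci_high,
                 covered = est$ci_low <= target & target <= est$ci_high,
                 failed = FALSE)
    }, error = function(e) {
      data.frame(rep = i, point = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, covered = NA, failed = TRUE)
    })
  }
  log <- do.call(rbind, rows)
  n_failed <- sum(log$failed)
  if (n_failed > 0.1 * reps) {
    stop(n_failed, "/", reps, " coverage replicates failed", call. = FALSE)
  }
  ok <- !log$failed
  structure(
    list(coverage = mean(log$covered[ok]), true_median = target,
         n_reps = reps, n_failed_reps = n_failed, B = B, seed = seed,
         log = log),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("Bootstrap-interval coverage: ", format(signif(x$coverage, 4)),
      " over ", x$n_reps - x$n_failed_reps, " replicates (",
      x$n_failed_reps, " failed), true median ",
      format(signif(x$true_median, 5)), " days, B = ", x$B, "\n", sep = "")
  invisible(x)
}
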