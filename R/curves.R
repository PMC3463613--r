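#' Logit-polynomial survival curves
#'
#' A `survival_curve` is the ground truth used by the synthetic-data
#' generator: survival probability is modelled as
#' \eqn{S(t) = \mathrm{logit}^{-1}(\sum_k \beta_k t^k)} over a time window in
#' days. The same polynomial-logit form is what [fit_logistic_survival()]
#' estimates from count data, so generator and model share one family.
#'
#' @param coefficients Numeric vector of logit-scale polynomial coefficients
#'   `(beta0, beta1, ...)`, lowest order first; units logit / day^k for the
#'   k-th order term.
#' @param time_window Length-2 numeric, start and end of the validity window
#'   in days (`start < end`, both non-negative).
#' @return An object of class `survival_curve` with elements `coefficients`,
#'   `time_window` and `true_median` (the descending 50% crossing, or `NA`
#'   when the curve never falls through 50% inside the window).
#' @examples
#' cv <- survival_curve(c(5, -0.25), c(0, 40))
#' cv$true_median  # 20: closed form -beta0/beta1
#' @seealso [true_median()], [simulate_lifespan_series()]
#' @export
survival_curve <- function(coefficients, time_window) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1L || anyNA(coefficients)) {
    stop("'coefficients' must be a non-empty numeric vector", call. = FALSE)
  }
  time_window <- as.numeric(time_window)
  if (length(time_window) != 2L || anyNA(time_window) ||
      time_window[1] < 0 || time_window[1] >= time_window[2]) {
    stop("'time_window' must be two non-negative days with start < end",
         call. = FALSE)
  }
  med <- tryCatch(
    descending_root(coefficients, time_window),
    error = function(e) NA_real_
  )
  structure(
    list(coefficients = coefficients, time_window = time_window,
         true_median = med),
    class = "survival_curve"
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Logit-polynomial survival curve (degree ",
      length(x$coefficients) - 1L, ")\n", sep = "")
  cat("  coefficients:", paste(signif(x$coefficients, 6), collapse = ", "),
      "\n")
  cat("  window: [", x$time_window[1], ", ", x$time_window[2], "] days\n",
      sep = "")
  if (is.na(x$true_median)) {
    cat("  median: not reached within window\n")
  } else {
    cat("  median:", format(x$true_median, digits = 6), "days\n")
  }
  invisible(x)
}

# Horner evaluation of the logit polynomial eta(t) = sum beta_k t^k.
eval_logit_poly <- function(coefficients, t) {
  eta <- rep(coefficients[length(coefficients)], length(t))
  for (k in seq(length(coefficients) - 1L, 1L, length.out =
                  length(coefficients) - 1L)) {
    eta <- eta * t + coefficients[k]
  }
  eta
}

#' Survival probability of a curve at given times
#'
#' @param curve A [survival_curve()].
#' @param t Numeric vector of times (days).
#' @return Numeric vector of survival probabilities in (0, 1).
#' @export
curve_survival <- function(curve, t) {
  stats::plogis(eval_logit_poly(curve$coefficients, t))
}

# Locate the unique descending root of eta(t) = 0 in `window`:
# dense grid scan for sign changes, then bisection to `tol` days.
# Descending means eta passes positive -> negative (survival falls
# through 50%). Errors when no or several descending crossings exist.
descending_root <- function(coefficients, window, n_grid = 10001L,
                            tol = 1e-9) {
  grid <- seq(window[1], window[2], length.out = n_grid)
  eta <- eval_logit_poly(coefficients, grid)
  down <- which(eta[-n_grid] > 0 & eta[-1L] <= 0)
  # a grid point landing exactly on zero with eta falling also qualifies
  if (length(down) == 0L) {
    stop("curve never reaches 50% in window [", window[1], ", ", window[2],
         "]", call. = FALSE)
  }
  if (length(down) > 1L) {
    stop("multiple descending 50% crossings near t = ",
         paste(signif(grid[down], 6), collapse = ", "),
         "; narrow the window", call. = FALSE)
  }
  lo <- grid[down]
  hi <- grid[down + 1L]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eval_logit_poly(coefficients, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' True median lifespan of a generating curve
#'
#' The median lifespan is the time at which 50% of nematodes are alive,
#' i.e. the descending root of the logit polynomial inside the curve's
#' window. Found by a dense grid scan followed by bisection.
#'
#' @param curve A [survival_curve()].
#' @param n_grid Number of grid points for the sign-change scan.
#' @return The median in days.
#' @examples
#' true_median(survival_curve(c(4.1589, -0.27726), c(0, 40)))  # 15.0
#' @export
true_median <- function(curve, n_grid = 10001L) {
  descending_root(curve$coefficients, curve$time_window, n_grid = n_grid)
}
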