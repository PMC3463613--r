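#' Sampling design of a lifespan assay
#'
#' Describes how a lifespan experiment samples the population: which days
#' are scored, how many worms are scored per day, and how much
#' extra-binomial variability the counts carry. The defaults mirror a
#' liquid-culture assay in which roughly 100 worms are scored alive or dead
#' every two days from day 2 to day 34.
#'
#' @param timepoints Strictly increasing numeric vector of sampling days.
#' @param n_per_timepoint Positive integer, worms scored per timepoint
#'   (default 100).
#' @param overdispersion_rho Beta-binomial intra-class correlation in
#'   `[0, 1)`; 0 gives pure binomial counts.
#' @param seed Integer RNG seed (mandatory; every simulated series is
#'   reproducible).
#' @return An object of class `lifespan_design`.
#' @export
lifespan_design <- function(timepoints = seq(2, 34, by = 2),
                            n_per_timepoint = 100L,
                            overdispersion_rho = 0,
                            seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 1L || any(diff(timepoints) <= 0)) {
    stop("'timepoints' must be strictly increasing", call. = FALSE)
  }
  n_per_timepoint <- as.integer(n_per_timepoint)
  if (is.na(n_per_timepoint) || n_per_timepoint < 1L) {
    stop("'n_per_timepoint' must be >= 1", call. = FALSE)
  }
  if (overdispersion_rho < 0 || overdispersion_rho >= 1) {
    stop("'overdispersion_rho' must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(timepoints = timepoints, n_per_timepoint = n_per_timepoint,
         overdispersion_rho = overdispersion_rho,
         seed = as.integer(seed)),
    class = "lifespan_design"
  )
}

#' Simulate a lifespan count series from a known survival curve
#'
#' Draws, for each design timepoint t, the number alive out of
#' `n_per_timepoint` scored worms. With `overdispersion_rho = 0` counts are
#' Binomial(n, S(t)); with rho > 0 they are beta-binomial with the same mean
#' and intra-class correlation rho, inflating the variance by the factor
#' 1 + (n - 1) * rho. The same seed always yields the same series.
#'
#' @param curve A [survival_curve()] valid over all design timepoints.
#' @param design A [lifespan_design()].
#' @return A [survival_series()] carrying the treatment label
#'   `"simulated"`.
#' @export
simulate_lifespan_series <- function(curve, design) {
  stopifnot(inherits(curve, "survival_curve"),
            inherits(design, "lifespan_design"))
  outside <- design$timepoints[design$timepoints < curve$time_window[1] |
                                 design$timepoints > curve$time_window[2]]
  if (length(outside) > 0L) {
    stop("timepoint ", outside[1], " lies outside the curve window [",
         curve$time_window[1], ", ", curve$time_window[2], "]",
         call. = FALSE)
  }
  s <- curve_survival(curve, design$timepoints)
  n <- design$n_per_timepoint
  rho <- design$overdispersion_rho
  alive <- withr::with_seed(design$seed, {
    if (rho == 0) {
      stats::rbinom(length(s), n, s)
    } else {
      # mean-preserving beta-binomial: p ~ Beta(s*c, (1-s)*c), c = (1-rho)/rho
      conc <- (1 - rho) / rho
      p <- stats::rbeta(length(s), s * conc, (1 - s) * conc)
      stats::rbinom(length(s), n, p)
    }
  })
  survival_series(design$timepoints, rep(n, length(s)), alive,
                  treatment = "simulated")
}
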