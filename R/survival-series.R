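#' Per-timepoint survival counts for one treatment arm
#'
#' The raw material of a lifespan assay: at each sampling day a fixed number
#' of nematodes is scored alive or dead under a microscope, and the series
#' records how many were scored and how many were alive.
#'
#' @param timepoints Strictly increasing numeric vector of sampling days.
#' @param n_scored Positive integer vector, worms scored at each timepoint.
#' @param n_alive Integer vector, worms alive at each timepoint
#'   (`0 <= n_alive <= n_scored`).
#' @param treatment Single character label for the arm.
#' @return An object of class `survival_series`.
#' @export
survival_series <- function(timepoints, n_scored, n_alive,
                            treatment = "untreated") {
  timepoints <- as.numeric(timepoints)
  n_scored <- as.integer(n_scored)
  n_alive <- as.integer(n_alive)
  k <- length(timepoints)
  if (k < 2L) {
    stop("a survival series needs at least 2 timepoints", call. = FALSE)
  }
  if (any(diff(timepoints) <= 0)) {
    stop("'timepoints' must be strictly increasing", call. = FALSE)
  }
  if (length(n_scored) != k || length(n_alive) != k) {
    stop("'n_scored' and 'n_alive' must match 'timepoints' in length",
         call. = FALSE)
  }
  if (any(n_scored < 1L)) stop("'n_scored' must be >= 1", call. = FALSE)
  if (any(n_alive < 0L) || any(n_alive > n_scored)) {
    stop("need 0 <= n_alive <= n_scored at every timepoint", call. = FALSE)
  }
  structure(
    list(timepoints = timepoints, n_scored = n_scored, n_alive = n_alive,
         treatment = as.character(treatment)[1]),
    class = "survival_series"
  )
}

#' @export
print.survival_series <- function(x, ...) {
  cat("Survival series '", x$treatment, "': ", length(x$timepoints),
      " timepoints, day ", x$timepoints[1], " to ",
      x$timepoints[length(x$timepoints)], "\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.survival_series <- function(x, ...) {
  data.frame(
    timepoint_days = x$timepoints,
    n_scored = x$n_scored,
    n_alive = x$n_alive,
    treatment = x$treatment,
    stringsAsFactors = FALSE
  )
}
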