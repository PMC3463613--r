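# Independent oracles used to cross-check the package's estimators.
# Nothing here calls the package's own fitting or root-finding code paths.

# binomial log-likelihood of a logit-polynomial model (raw time scale)
binom_loglik <- function(beta, t, n, y) {
  eta <- vapply(t, function(ti) sum(beta * ti^(seq_along(beta) - 1L)),
                numeric(1))
  sum(stats::dbinom(y, n, stats::plogis(eta), log = TRUE))
}

# Brute-force maximizer of the binomial log-likelihood for a degree-1
# model: coarse grid over (intercept, slope), refined with Nelder-Mead.
grid_mle_degree1 <- function(t, n, y,
                             b0 = seq(-20, 20, length.out = 161),
                             b1 = seq(-2, 2, length.out = 161)) {
  grid <- expand.grid(b0 = b0, b1 = b1)
  ll <- mapply(function(a, b) binom_loglik(c(a, b), t, n, y),
               grid$b0, grid$b1)
  start <- as.numeric(grid[which.max(ll), ])
  refined <- stats::optim(start, function(beta)
    -binom_loglik(beta, t, n, y),
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000))
  refined$par
}

# Multi-start Nelder-Mead likelihood-surface search for arbitrary degree,
# on a centred time axis for conditioning (starts are fixed perturbations,
# independent of any IRLS state).
surface_mle <- function(t, n, y, degree, n_starts = 12L) {
  tc <- t - mean(t)
  nll <- function(g) -binom_loglik(g, tc, n, y)
  starts <- rbind(
    rep(0, degree + 1L),
    diag(degree + 1L) * 0.5,
    -diag(degree + 1L) * 0.5
  )
  set.seed(99)
  starts <- rbind(starts,
                  matrix(stats::rnorm(n_starts * (degree + 1L), 0, 0.5),
                         ncol = degree + 1L))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    r <- tryCatch(
      stats::optim(starts[i, ], nll, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 20000)),
      error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
  }
  # map centred coefficients back to the raw time scale
  g <- best$par
  m <- mean(t)
  beta <- numeric(degree + 1L)
  for (k in 0:degree) {
    for (j in 0:k) {
      beta[j + 1L] <- beta[j + 1L] + g[k + 1L] * choose(k, j) * (-m)^(k - j)
    }
  }
  beta
}

# uniroot-based median oracle: descending 50% crossing of the logit
# polynomial, independent of the package's grid+bisection path.
uniroot_median <- function(beta, window) {
  f <- function(t) vapply(t, function(ti)
    sum(beta * ti^(seq_along(beta) - 1L)), numeric(1))
  g <- seq(window[1], window[2], length.out = 4001)
  e <- f(g)
  i <- which(e[-length(e)] > 0 & e[-1] <= 0)[1]
  stats::uniroot(f, c(g[i], g[i + 1]), tol = 1e-12)$root
}

# survival_fit skeleton with known coefficients, for testing prediction
# and curve inversion in isolation from fitting
fake_fit <- function(coefficients, data_window, degree = NULL) {
  if (is.null(degree)) degree <- if (length(coefficients) > 2) 3L else 1L
  structure(
    list(coefficients = coefficients, data_window = data_window,
         config = model_config(degree = degree), converged = TRUE,
         treatment = "synthetic"),
    class = "survival_fit"
  )
}

# three-sigma Monte-Carlo band for a sample variance, using the sample's
# own fourth moment
var_mc_band <- function(x) {
  m <- length(x)
  s2 <- stats::var(x)
  mu4 <- mean((x - mean(x))^4)
  se <- sqrt((mu4 - (m - 3) / (m - 1) * s2^2) / m)
  c(s2 - 3 * se, s2 + 3 * se, s2 = s2, se = se)
}
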