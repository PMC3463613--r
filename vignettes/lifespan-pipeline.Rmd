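---
title: "Methods: survival-curve inference and plate normalization in lumispan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival-curve inference and plate normalization in lumispan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumispan)
```

## The survival model

A lifespan assay in liquid culture scores a sample of worms alive or dead
at each timepoint: at day $t_i$, $y_i$ of $n_i$ scored worms are alive.
lumispan models the survival proportion as a binomial logistic regression
with a polynomial time trend,

$$\mathrm{logit}\, S(t) = \beta_0 + \beta_1 t + \dots + \beta_d t^d,
\qquad y_i \sim \mathrm{Binomial}(n_i, S(t_i)),$$

with $d \in \{1, 3\}$. A linear logit suits unmanipulated survival data;
a cubic accommodates the early plateau and long tail typical when progeny
production is blocked with FUdR. Other degrees are rejected outright
(`model_config()`), because intermediate even degrees produce logits that
cannot describe a survival curve falling monotonically through 50% and
silently accepting them invites misuse.

Three assumptions matter. First, every worm in the culture is available
for sampling at every timepoint, so the per-timepoint proportions are
unbiased estimates of $S(t_i)$; sampling *without* replacement from a
finite, shrinking population is not modelled. Second, timepoints are
independent given the curve — there is no serial correlation beyond what
the smooth trend captures. Third, extra-binomial variability exists but
is adequately described by a single dispersion factor.

### Estimation

`fit_logistic_survival()` maximizes the binomial likelihood by
iteratively reweighted least squares (IRLS). Numerical choices:

* **Conditioning.** The time covariate is centred and scaled internally
  ($z = (t - \bar t)/s_t$); with raw days up to 34, a cubic design matrix
  spans five orders of magnitude, and the scaled basis keeps the
  information matrix well conditioned. Coefficients and covariance are
  mapped back to the raw day scale before being reported, via the exact
  linear transform between the two polynomial bases.
* **Initialisation.** Empirical logits with a Haldane correction,
  $\mathrm{logit}\big((y_i + 0.5)/(n_i + 1)\big)$, regressed on the
  design. The correction keeps the start finite when end-of-series counts
  are 0 or $n$.
* **Convergence.** Maximum absolute coefficient change below `tolerance`
  (default $10^{-8}$), at most `max_iterations` (default 100) steps.
  Non-convergence is a warning and a `converged = FALSE` flag, not an
  error, so bootstrap loops can discard such fits deliberately.
* **Separation.** When the likelihood has no finite maximizer (e.g. all
  survival before a gap, none after), fitted logits diverge; the fit
  aborts with an explicit error once $|\eta| > 30$ at any data point.
* **Degenerate inputs.** Fewer than $d + 1$ timepoints, or all-zero /
  all-$n$ counts, are rejected before fitting.

### Overdispersion

Observed counts in these assays are more variable than binomial — worms
clump, pipetted samples are not perfect random draws. The model therefore
carries a quasi-binomial dispersion
$$\hat\varphi = \frac{1}{k - (d+1)} \sum_i
  \frac{(y_i - n_i \hat p_i)^2}{n_i \hat p_i (1 - \hat p_i)},$$
the Pearson moment estimator, which scales the coefficient covariance.
Two design choices here were genuinely open:

* **Pearson vs deviance.** Either statistic over its degrees of freedom
  is a standard moment estimator; Pearson is the default because it is
  the conventional quasi-likelihood choice and remains finite for
  boundary counts. The deviance is still reported in the fit object.
* **Flooring at 1.** `dispersion_floor = 1` means apparent
  *under*dispersion (common in small series by chance, e.g. the 4-point
  worked example has $\hat\varphi \approx 0.03$) never shrinks standard
  errors. The rationale is one-sided: the dispersion term exists to admit
  *greater* variability than binomial, not to reward small samples.
  A saturated fit ($k = d + 1$) has no residual degrees of freedom;
  `pearson_dispersion()` refuses it and the covariance falls back to the
  floor.

## Median lifespan and its interval

The median lifespan is the day the fitted curve falls through 50%, i.e.
the root of the fitted logit polynomial. `estimate_median()` scans a
dense grid (2001 points) over the data window widened by 25% on each side
and refines the bracketing interval by bisection to $10^{-9}$ days. A
cubic can cross zero three times; the rule is to accept only crossings
where the logit passes positive to negative (survival *falling* through
50%), to error if none exists ("median not reached"), and — rather than
guessing — to error listing all candidates if several descending
crossings fall inside the window, at which point the caller narrows it.
The 25% widening is a compromise: it tolerates modest extrapolation when
the observed series ends slightly above 50%, while keeping the cubic's
spurious outer roots out of reach.

`bootstrap_median_ci()` attaches a percentile-bootstrap interval. Each
resample redraws the number alive at every timepoint from
$\mathrm{Binomial}(n_i, \hat p_i)$ with $\hat p_i$ the **observed**
proportion, refits the model, and recomputes the median; the 2.5th and
97.5th percentiles of the $B$ bootstrap medians (linear interpolation
between order statistics — `stats::quantile()` type 7, documented
bit-exactly because percentile conventions differ) form the interval.
Further open choices, and what was decided:

* **Observed vs fitted proportions.** Resampling at observed proportions
  is the default; smoothing the resampling distribution through the
  fitted curve is available via `resample = "fitted"` but changes the
  interval's character (it then reflects only model-consistent noise).
* **$B$.** Default 1000; 200–300 is enough for stable 95% limits and is
  used in the heavier validation runs.
* **Overdispersion is not injected into resamples.** Resampling is plain
  binomial; when the data truly carry intra-class correlation
  $\rho > 0$ the interval will undercover. Beta-binomial resampling is
  exposed (`resample_rho`) for sensitivity analysis but is off by
  default, matching the plain-binomial definition of the procedure.
* **Failed resamples** (fit failure or no descending crossing) are
  excluded and counted; more than 5% of them aborts the interval with
  advice to widen the window or lower the degree, because a percentile of
  a censored bootstrap sample is no longer trustworthy.

`coverage_experiment()` closes the loop: it simulates many series from a
known curve, builds the interval for each, and reports how often the true
median is covered. With 200 replicates, $B = 300$, 100 worms per
timepoint every 2 days over days 2–34, and a cubic fit, coverage of the
nominal 95% interval sits in the low-to-mid 90s — the familiar mild
undercoverage of percentile intervals at moderate information — and the
validation band used in the test suite is [0.91, 0.98], the three-sigma
Monte-Carlo range around 0.95 at 200 replicates.

## The synthetic-data generators

`simulate_lifespan_series()` inverts the estimation model: given a true
logit-polynomial curve, it draws per-timepoint counts
$\mathrm{Binomial}(n, S(t))$, or beta-binomial with matching mean and
intra-class correlation $\rho$ when `overdispersion_rho > 0` (a
single-parameter, mean-preserving inflation — the mechanism behind real
overdispersion is unknown, and beta-binomial is the minimal choice). The
default design — 100 worms per timepoint, every 2 days from day 2 to
day 34 — spans the range of median lifespans such assays produce
(roughly 10 to 25 days depending on FUdR concentration).

`simulate_plate()` emulates the well-level structure of the plate assay:

* worm count per well: rounded $\mathrm{Normal}(30, 5.1)$ truncated by
  rejection to $[17, 45]$ — calibrated to observed per-column means and
  SEMs ($30.0 \pm 1.8$ over 8 wells $\Rightarrow$ SD
  $\approx 1.8\sqrt{8} \approx 5.1$) and the observed extremes;
* luminescence: count × per-worm yield × treatment multiplier × a
  log-normal factor with unit mean and CV `noise_cv` (a positive-valued
  signal with replicate-level CVs reported, and no stated distribution,
  makes multiplicative log-normal the natural choice);
* fluorescence: count × per-worm yield + additive background.

Treatment effects are phenomenological multipliers on the light signal —
no ATP kinetics, growth or development is simulated. Each simulated
series is one pooled arm; whether real scoring pooled across culture
flasks is not modelled. What passing tests on these generators show is
therefore that the *inference machinery* is correct under its own
assumptions; they cannot show robustness to features real data may have
(serial correlation between timepoints, flask effects, count-dependent
scoring error).

## Plate normalization

`subtract_background()` clamps at zero and counts clamped wells.
`group_wells_to_replicates()` averages `group_size` wells (default 8 =
one plate column; fewer than 5 is refused) into one technical replicate
in column order, erroring on leftover wells rather than silently
averaging ragged groups. `percent_of_control()` divides the mean of
treatment replicate means by the mean of control replicate means per
timepoint, × 100, so the control arm is exactly 100 by construction. Two
conventions were open:

* **Control pooling.** Control means are pooled per timepoint across
  plates (rather than normalizing within each plate); with balanced
  designs the two agree in expectation and the pooled version is simpler
  and stabler.
* **Error propagation.** The reported SEM reflects the spread of the
  treatment replicates only; the control mean is treated as a fixed
  scale. Propagating control variance into a ratio SEM is possible but
  conflates the two arms' precision in a way plate summaries of this kind
  conventionally avoid.

A consequence worth stating: because well worm-counts vary with CV
$\approx 0.17$, the sampling SD of a percent-of-control value built from
3 replicates of 8 wells per arm is about
$100 \times e \times \sqrt{0.17^2 + \mathrm{cv}^2}\,\sqrt{2/24}$ points
(for effect $e$) — roughly 3 points at $e = 0.55$,
$\mathrm{cv} = 0.1$. Worm-number variability, not reader noise,
dominates the uncertainty of the normalized value at this design size,
which is exactly why wells are aggregated into ≥5-well technical
replicates in the first place.

## Problem sizes

The validation suite runs at the sizes the procedures are designed for:
coverage at 200 replicate series × 300 bootstrap resamples; parameter
recovery at 200 seeds with 1000 worms per timepoint; the plate pipeline
loop at 500 seeds of 3 × 8 wells per arm. These sizes give Monte-Carlo
standard errors small enough that the assertions are informative (e.g.
±1.5 percentage points on a coverage estimate) while a full test run
completes in about a minute.

## Known limitations

* Percentile intervals mildly undercover at $n \approx 100$ per
  timepoint; BCa or accelerated variants are out of scope.
* Binomial resampling ignores overdispersion; with $\rho > 0$ intervals
  undercover further (quantifiable with `coverage_experiment()` at
  `overdispersion_rho > 0`).
* The median is defined by the *fitted* curve; with a cubic, the
  estimate inherits the cubic's extrapolation behaviour near the window
  edges.
* Between-treatment significance testing (treatment × time interaction
  models) is deliberately not implemented; the package estimates, it
  does not test.
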