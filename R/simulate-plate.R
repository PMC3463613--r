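#' Configuration of the 96-well plate simulator
#'
#' Emulates a bioluminescence/fluorescence plate assay in which wells are
#' seeded from a shaken liquid worm culture. Worm counts per well follow a
#' rounded normal distribution truncated to an observed range, and the
#' light signal of a well scales with its worm count. Defaults reproduce a
#' dispensing protocol averaging 30 worms per well (SD 5.1, the SEM of an
#' 8-well column times sqrt(8)) with observed extremes 17 and 45.
#'
#' @param mean_worms_per_well Mean worms per well before truncation
#'   (default 30).
#' @param sd_worms_per_well SD of worms per well (default 5.1).
#' @param min_worms,max_worms Truncation bounds on the per-well count
#'   (defaults 17 and 45).
#' @param per_worm_yield Luminescence per worm, relative light units
#'   (default 10).
#' @param per_worm_fluorescence Fluorescence per worm, arbitrary
#'   fluorescence units (default 5).
#' @param treatment_effects Named positive numeric vector mapping treatment
#'   label to a multiplicative luminescence effect; the solvent control has
#'   effect 1 (default `c(DMSO = 1)`).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal well noise on luminescence (default 0.1).
#' @param background_fluorescence Additive fluorescence background
#'   (default 0).
#' @param wells_per_replicate Wells aggregated into one technical
#'   replicate, at least 5 (default 8, one plate column).
#' @param seed Integer RNG seed (required).
#' @return An object of class `plate_sim_config`.
#' @export
plate_sim_config <- function(mean_worms_per_well = 30,
                             sd_worms_per_well = 5.1,
                             min_worms = 17L, max_worms = 45L,
                             per_worm_yield = 10,
                             per_worm_fluorescence = 5,
                             treatment_effects = c(DMSO = 1),
                             noise_cv = 0.1,
                             background_fluorescence = 0,
                             wells_per_replicate = 8L,
                             seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  min_worms <- as.integer(min_worms)
  max_worms <- as.integer(max_worms)
  if (min_worms > max_worms) {
    stop("'min_worms' must not exceed 'max_worms'", call. = FALSE)
  }
  if (wells_per_replicate < 5L) {
    stop("'wells_per_replicate' must be >= 5 (minimum of 5 wells per ",
         "technical replicate)", call. = FALSE)
  }
  if (is.null(names(treatment_effects)) ||
      any(!nzchar(names(treatment_effects)))) {
    stop("'treatment_effects' must be a named vector", call. = FALSE)
  }
  if (any(treatment_effects <= 0)) {
    stop("'treatment_effects' must be positive multipliers", call. = FALSE)
  }
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  structure(
    list(mean_worms_per_well = mean_worms_per_well,
         sd_worms_per_well = sd_worms_per_well,
         min_worms = min_worms, max_worms = max_worms,
         per_worm_yield = per_worm_yield,
         per_worm_fluorescence = per_worm_fluorescence,
         treatment_effects = treatment_effects,
         noise_cv = noise_cv,
         background_fluorescence = background_fluorescence,
         wells_per_replicate = as.integer(wells_per_replicate),
         seed = as.integer(seed)),
    class = "plate_sim_config"
  )
}

# rounded Normal truncated to [lo, hi] by rejection resampling
rtrunc_count <- function(n, mean, sd, lo, hi) {
  x <- as.integer(round(stats::rnorm(n, mean, sd)))
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0L) {
    x[bad] <- as.integer(round(stats::rnorm(length(bad), mean, sd)))
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate raw 96-well plate readings
#'
#' Generates one well record per well: the worm count is a rounded
#' truncated-normal draw; luminescence is
#' count x per-worm yield x treatment effect x a log-normal noise factor
#' with unit mean and CV `noise_cv`; fluorescence is count x per-worm
#' fluorescence plus the additive background. Wells are laid out down
#' plate columns (A1..H1, A2..H2, ...), one treatment after another,
#' rolling over to a new plate every 96 wells. The same seed always yields
#' the same plate.
#'
#' @param config A [plate_sim_config()].
#' @param n_wells_per_treatment Wells per treatment, at least
#'   `wells_per_replicate`.
#' @param timepoint_h Assay timepoint in hours (default 4).
#' @param treatments Treatment labels to simulate; defaults to all labels
#'   in `config$treatment_effects`. A label without a configured effect is
#'   an error.
#' @return A data frame of well records with columns `plate_id`, `well`,
#'   `row`, `col`, `treatment`, `timepoint_h`, `worm_count`,
#'   `luminescence`, `fluorescence`.
#' @export
simulate_plate <- function(config, n_wells_per_treatment,
                           timepoint_h = 4,
                           treatments = names(config$treatment_effects)) {
  stopifnot(inherits(config, "plate_sim_config"))
  n_wells_per_treatment <- as.integer(n_wells_per_treatment)
  if (n_wells_per_treatment < config$wells_per_replicate) {
    stop("'n_wells_per_treatment' must be >= wells_per_replicate (",
         config$wells_per_replicate, ")", call. = FALSE)
  }
  missing_trt <- setdiff(treatments, names(config$treatment_effects))
  if (length(missing_trt) > 0L) {
    stop("no treatment effect configured for '", missing_trt[1], "'",
         call. = FALSE)
  }

  n_total <- n_wells_per_treatment * length(treatments)
  trt <- rep(treatments, each = n_wells_per_treatment)
  effect <- unname(config$treatment_effects[trt])

  dat <- withr::with_seed(config$seed, {
    count <- rtrunc_count(n_total, config$mean_worms_per_well,
                          config$sd_worms_per_well,
                          config$min_worms, config$max_worms)
    noise <- if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      stats::rlnorm(n_total, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, n_total)
    }
    lum <- count * config$per_worm_yield * effect * noise
    fluo <- count * config$per_worm_fluorescence +
      config$background_fluorescence
    list(count = count, lum = lum, fluo = fluo)
  })

  idx <- seq_len(n_total) - 1L
  within_plate <- idx %% 96L
  row <- LETTERS[within_plate %% 8L + 1L]
  col <- within_plate %/% 8L + 1L
  data.frame(
    plate_id = sprintf("P%02d", idx %/% 96L + 1L),
    well = paste0(row, col),
    row = row,
    col = col,
    treatment = trt,
    timepoint_h = timepoint_h,
    worm_count = dat$count,
    luminescence = dat$lum,
    fluorescence = dat$fluo,
    stringsAsFactors = FALSE
  )
}
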