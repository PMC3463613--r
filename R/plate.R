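#' Subtract a background reading from one plate channel
#'
#' Replaces the chosen channel by `max(value - background, 0)`. Wells that
#' would go negative are clamped to zero; the number of clamped wells is
#' attached as attribute `"n_clamped"` and reported with a message.
#'
#' @param records Well-record data frame (see [simulate_plate()] for the
#'   layout).
#' @param background Non-negative background reading in the channel's
#'   units.
#' @param channel `"luminescence"` or `"fluorescence"`.
#' @return The records with the channel background-subtracted.
#' @export
subtract_background <- function(records, background,
                                channel = c("fluorescence",
                                            "luminescence")) {
  channel <- match.arg(channel)
  if (background < 0) stop("'background' must be >= 0", call. = FALSE)
  v <- records[[channel]] - background
  n_clamped <- sum(v < 0)
  if (n_clamped > 0L) {
    message(n_clamped, " well(s) clamped to zero after background ",
            "subtraction in ", channel)
  }
  records[[channel]] <- pmax(v, 0)
  attr(records, "n_clamped") <- n_clamped
  records
}

#' Aggregate wells into technical replicates
#'
#' Because worm numbers vary from well to well, a single well is too noisy
#' to treat as an observation; the average of a group of wells (one plate
#' column of 8 by default, never fewer than 5) is taken as one technical
#' replicate. Wells are grouped within each (treatment, timepoint) in
#' column order (plate, then column, then row); leftover wells that do not
#' fill a complete group are an error, as is any group size below 5.
#'
#' @param records Well-record data frame.
#' @param group_size Wells per technical replicate, at least 5 (default 8).
#' @return A data frame with one row per technical replicate: `treatment`,
#'   `timepoint_h`, `replicate`, `n_wells`, `mean_luminescence`,
#'   `sem_luminescence`.
#' @examples
#' pl <- simulate_plate(plate_sim_config(seed = 1), 16)
#' group_wells_to_replicates(pl)
#' @export
group_wells_to_replicates <- function(records, group_size = 8L) {
  group_size <- as.integer(group_size)
  if (group_size < 5L) {
    stop("'group_size' must be >= 5: a technical replicate is the mean ",
         "of a minimum of 5 wells", call. = FALSE)
  }
  ord <- order(records$treatment, records$timepoint_h, records$plate_id,
               records$col, records$row)
  records <- records[ord, , drop = FALSE]
  key <- paste(records$treatment, records$timepoint_h, sep = "\r")
  pieces <- split(records, key)

  out <- lapply(pieces, function(g) {
    n <- nrow(g)
    if (n %% group_size != 0L) {
      left <- g[(n - n %% group_size + 1L):n, , drop = FALSE]
      stop("wells for treatment '", g$treatment[1], "' at ",
           g$timepoint_h[1], " h do not fill complete groups of ",
           group_size, "; leftover wells: ",
           paste(left$plate_id, left$well, sep = ":", collapse = ", "),
           call. = FALSE)
    }
    rep_id <- rep(seq_len(n %/% group_size), each = group_size)
    means <- tapply(g$luminescence, rep_id, mean)
    sds <- tapply(g$luminescence, rep_id, stats::sd)
    data.frame(
      treatment = g$treatment[1],
      timepoint_h = g$timepoint_h[1],
      replicate = seq_along(means),
      n_wells = group_size,
      mean_luminescence = as.numeric(means),
      sem_luminescence = as.numeric(sds) / sqrt(group_size),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Express replicate luminescence as percent of the solvent control
#'
#' For every (treatment, timepoint) the mean of the technical-replicate
#' means is divided by the mean of the control replicates at the same
#' timepoint and multiplied by 100. The control arm itself is therefore
#' exactly 100 at every timepoint. The SEM is propagated from the spread
#' of the treatment replicates only; the control mean is treated as the
#' normalizing scale.
#'
#' @param replicates Technical-replicate data frame from
#'   [group_wells_to_replicates()].
#' @param control_label Treatment label of the solvent control
#'   (default `"DMSO"`).
#' @return A data frame with columns `treatment`, `timepoint_h`,
#'   `percent_of_control`, `sem`, `n_replicates`.
#' @export
percent_of_control <- function(replicates, control_label = "DMSO") {
  tps <- sort(unique(replicates$timepoint_h))
  out <- list()
  for (tp in tps) {
    at_tp <- replicates[replicates$timepoint_h == tp, , drop = FALSE]
    ctrl <- at_tp$mean_luminescence[at_tp$treatment == control_label]
    if (length(ctrl) == 0L) {
      stop("no '", control_label, "' control replicates at timepoint ",
           tp, " h", call. = FALSE)
    }
    ctrl_mean <- mean(ctrl)
    if (ctrl_mean <= 0) {
      stop("control mean luminescence is not positive at timepoint ", tp,
           " h", call. = FALSE)
    }
    for (trt in unique(at_tp$treatment)) {
      v <- at_tp$mean_luminescence[at_tp$treatment == trt]
      sem <- if (length(v) > 1L) {
        100 * stats::sd(v) / sqrt(length(v)) / ctrl_mean
      } else {
        NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        treatment = trt,
        timepoint_h = tp,
        percent_of_control = 100 * mean(v) / ctrl_mean,
        sem = sem,
        n_replicates = length(v),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
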