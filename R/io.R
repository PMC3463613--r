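SURVIVAL_CSV_HEADER <- c("timepoint_days", "n_scored", "n_alive",
                         "treatment")
PLATE_CSV_HEADER <- c("plate_id", "well", "row", "col", "treatment",
                      "timepoint_h", "worm_count", "luminescence",
                      "fluorescence")

#' Read survival-count series from CSV
#'
#' Expects the exact header `timepoint_days,n_scored,n_alive,treatment`.
#' Rows are validated (numeric fields, `n_alive <= n_scored`) with the
#' offending file line named in any error, split by treatment, and sorted
#' by timepoint within each arm.
#'
#' @param path Path to the CSV file.
#' @return A named list of [survival_series()], one per treatment.
#' @export
read_survival_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), SURVIVAL_CSV_HEADER)) {
    stop("expected header '",
         paste(SURVIVAL_CSV_HEADER, collapse = ","), "' in ", path,
         call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  lines <- seq_len(nrow(raw)) + 1L   # file line numbers (header = line 1)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop("non-numeric '", col, "' value '", raw[[col]][bad[1]],
           "' at line ", lines[bad[1]], " of ", path, call. = FALSE)
    }
    v
  }
  tp <- num("timepoint_days")
  scored <- num("n_scored")
  alive <- num("n_alive")
  bad <- which(alive > scored)
  if (length(bad) > 0L) {
    stop("n_alive (", alive[bad[1]], ") exceeds n_scored (",
         scored[bad[1]], ") at line ", lines[bad[1]], " of ", path,
         call. = FALSE)
  }
  out <- lapply(split(seq_len(nrow(raw)), raw$treatment), function(i) {
    i <- i[order(tp[i])]
    survival_series(tp[i], scored[i], alive[i],
                    treatment = raw$treatment[i[1]])
  })
  out[order(names(out))]
}

#' Write survival-count series to CSV
#'
#' @param series A [survival_series()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(series, path) {
  if (inherits(series, "survival_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write plate well records
#'
#' The plate CSV dialect has header
#' `plate_id,well,row,col,treatment,timepoint_h,worm_count,luminescence,fluorescence`
#' with wells in letter-number form (A1..H12).
#'
#' @param records Well-record data frame.
#' @param path CSV path.
#' @return `write_plate_csv` returns `path` invisibly; `read_plate_csv`
#'   returns the well-record data frame.
#' @export
write_plate_csv <- function(records, path) {
  stopifnot(all(PLATE_CSV_HEADER %in% names(records)))
  utils::write.csv(records[, PLATE_CSV_HEADER], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), PLATE_CSV_HEADER)) {
    stop("expected header '", paste(PLATE_CSV_HEADER, collapse = ","),
         "' in ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(df$luminescence < 0) || any(df$fluorescence < 0)) {
    stop("negative readings in ", path, call. = FALSE)
  }
  df
}

#' Serialize a fitted survival model as a JSON report
#'
#' @param model A `survival_fit`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
fit_report_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "survival_fit"))
  rep <- list(
    treatment = model$treatment,
    degree = model$config$degree,
    coefficients = model$coefficients,
    dispersion = model$dispersion,
    dispersion_raw = model$dispersion_raw,
    pearson_chi2 = model$pearson_chi2,
    deviance = model$deviance,
    df_residual = model$df_residual,
    converged = model$converged,
    data_window = model$data_window,
    config = unclass(model$config)
  )
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
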