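#' Read a concentration-time CSV
#'
#' Expects a header `time_h,conc_ng_ml`. Below-quantification tokens
#' (`<LLOQ`, `BLQ`, `BQL`, case-insensitive) are parsed as zero
#' concentration with the `blq` flag set. Times must be strictly
#' increasing; malformed or duplicate rows raise an error naming the line.
#'
#' @param path CSV path.
#' @return a [conc_series()].
#' @export
read_concentration_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0) stop("empty concentration file: ", path, call. = FALSE)
  need <- c("time_h", "conc_ng_ml")
  if (!all(need %in% names(df))) {
    stop("concentration file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  time <- suppressWarnings(as.numeric(df$time_h))
  raw <- trimws(df$conc_ng_ml)
  blq <- grepl("^(<\\s*LLOQ|BLQ|BQL)$", raw, ignore.case = TRUE)
  conc <- suppressWarnings(as.numeric(raw))
  conc[blq] <- 0
  bad <- which(!is.finite(time) | (!blq & !is.finite(conc)))
  if (length(bad) > 0) {
    stop("malformed row at line ", bad[1] + 1, " of ", path, call. = FALSE)
  }
  dup <- which(diff(time) <= 0)
  if (length(dup) > 0) {
    stop("times not strictly increasing at line ", dup[1] + 2, " of ", path,
         call. = FALSE)
  }
  conc_series(time, conc, blq = blq)
}

#' Write a concentration-time series to CSV
#'
#' @param series a [conc_series()] (or data frame with `time_h`,
#'   `conc_ng_ml`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concentration_csv <- function(series, path) {
  df <- data.frame(time_h = series$time_h, conc_ng_ml = series$conc_ng_ml)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standard 36-day intramuscular sampling schedule
#'
#' Pre-dose, 6 h, daily to day 12, then days 14, 16, 18, 20, 24, 28, 32 and
#' 36 — the 22-point schedule used for single-dose depot studies in dogs.
#'
#' @return numeric vector of 22 sampling times in hours.
#' @export
dog_schedule <- function() {
  c(0, 6, 24 * c(1:12, 14, 16, 18, 20, 24, 28, 32, 36))
}

#' Generate a noisy synthetic observed concentration curve
#'
#' Simulates the model, samples it at the given schedule and multiplies
#' each point by mean-one lognormal noise
#' (`exp(rnorm(0, sigma) - sigma^2 / 2)` with
#' `sigma = sqrt(log(1 + cv^2))`, so the expected value equals the model
#' curve). Values below the quantification limit are censored to zero with
#' the `blq` flag set. Used for fit-recovery and end-to-end tests in place
#' of unpublished raw in-vivo curves.
#'
#' @param spec a `depot_model_spec`.
#' @param schedule sampling times, hours.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param seed integer seed.
#' @param lloq censoring limit, ng/mL (default 0.5).
#' @return a [conc_series()] with `blq` flags.
#' @export
generate_synthetic_observed <- function(spec, schedule, noise_cv = 0, seed = 1,
                                        lloq = 0.5) {
  stopifnot(inherits(spec, "depot_model_spec"))
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  schedule <- sort(unique(round(as.numeric(schedule), 8)))
  grid <- if (schedule[1] > 0) c(0, schedule) else schedule
  sim <- simulate_depot(spec, max(schedule), output_times = grid)
  conc <- sim$plasma$conc_ng_ml[match(schedule, sim$plasma$time_h)]
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    fac <- .with_seed(seed, exp(stats::rnorm(length(conc), 0, sigma) - sigma^2 / 2))
    conc <- conc * fac
  }
  blq <- conc < lloq
  conc[blq] <- 0
  conc_series(schedule, conc, blq = blq)
}

#' Write percentile curves of a population summary to CSV
#'
#' Header `time_h,p5,p50,p95` (ng/mL).
#'
#' @param summary a `population_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_percentile_csv <- function(summary, path) {
  stopifnot(inherits(summary, "population_summary"))
  utils::write.csv(summary$percentile_curves, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
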