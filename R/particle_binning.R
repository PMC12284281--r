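#' Default cumulative-mass cutpoints for size binning
#'
#' The standard 12-bin mass-percentile scheme: fine tail resolved with 2%,
#' 3% and 5% bins, then nine 10% bins. Adjacent differences are the bin
#' mass fractions.
#'
#' @return numeric vector of 13 cumulative-mass cutpoints from 0 to 1.
#' @examples
#' diff(default_cut_fractions())
#' @export
default_cut_fractions <- function() {
  c(0, 0.02, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80, 0.90, 1.0)
}

#' Construct a particle-size distribution
#'
#' A cumulative mass-weighted particle-size distribution: for each diameter,
#' the fraction of total particle mass carried by particles at or below that
#' diameter (the quantity a laser-diffraction instrument reports).
#'
#' @param diameter_um particle diameters in micrometres, strictly increasing
#'   and positive.
#' @param cum_mass_fraction cumulative mass fraction in `[0, 1]`,
#'   non-decreasing; the last value must be 1 (within 1e-9).
#' @return a `psd` object (data frame with columns `diameter_um`,
#'   `cum_mass_fraction`).
#' @seealso [bin_psd()], [read_psd_csv()]
#' @export
particle_size_distribution <- function(diameter_um, cum_mass_fraction) {
  if (length(diameter_um) != length(cum_mass_fraction)) {
    stop("diameter and cumulative-fraction vectors must have equal length", call. = FALSE)
  }
  if (length(diameter_um) < 2) {
    stop("a particle-size distribution needs at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0)) {
    stop("diameters must be positive and finite", call. = FALSE)
  }
  if (any(diff(diameter_um) <= 0)) {
    stop("diameters must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(cum_mass_fraction)) || any(cum_mass_fraction < 0) ||
      any(cum_mass_fraction > 1 + 1e-9)) {
    stop("cumulative mass fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(cum_mass_fraction) < -1e-12)) {
    stop("cumulative mass fractions must be non-decreasing", call. = FALSE)
  }
  if (abs(cum_mass_fraction[length(cum_mass_fraction)] - 1) > 1e-9) {
    stop("the final cumulative mass fraction must equal 1", call. = FALSE)
  }
  out <- data.frame(diameter_um = as.numeric(diameter_um),
                    cum_mass_fraction = pmin(as.numeric(cum_mass_fraction), 1))
  class(out) <- c("psd", "data.frame")
  out
}

#' Read a particle-size distribution from CSV
#'
#' Expects a header `diameter_um,cum_mass_fraction` with rows ascending in
#' diameter.
#'
#' @param path path to the CSV file.
#' @return a `psd` object.
#' @export
read_psd_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("diameter_um", "cum_mass_fraction")
  if (!all(need %in% names(df))) {
    stop("PSD file must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  particle_size_distribution(df$diameter_um, df$cum_mass_fraction)
}

#' Construct a set of particle-size bins
#'
#' @param mass_fraction per-bin mass fractions, summing to 1 (within 1e-9).
#' @param mean_diameter_um per-bin mean diameters in micrometres,
#'   non-decreasing with bin index.
#' @param lag_time_h optional per-bin dissolution lag times in hours.
#' @param particle_count optional per-bin particle counts.
#' @param cut_fractions optional cumulative-mass cutpoints the bins came from.
#' @return a `size_bin_set` object (data frame with one row per bin).
#' @export
size_bin_set <- function(mass_fraction, mean_diameter_um, lag_time_h = NA_real_,
                         particle_count = NA_real_, cut_fractions = NULL) {
  n <- length(mass_fraction)
  if (length(mean_diameter_um) != n) {
    stop("mass_fraction and mean_diameter_um must have equal length", call. = FALSE)
  }
  if (any(mass_fraction <= 0)) stop("bin mass fractions must be positive", call. = FALSE)
  if (abs(sum(mass_fraction) - 1) > 1e-9) {
    stop("bin mass fractions must sum to 1", call. = FALSE)
  }
  if (any(mean_diameter_um <= 0)) stop("bin mean diameters must be positive", call. = FALSE)
  if (any(diff(mean_diameter_um) < -1e-12)) {
    stop("bin mean diameters must be non-decreasing with bin index", call. = FALSE)
  }
  lag_time_h <- rep_len(as.numeric(lag_time_h), n)
  if (any(!is.na(lag_time_h) & lag_time_h < 0)) {
    stop("lag times must be >= 0", call. = FALSE)
  }
  particle_count <- rep_len(as.numeric(particle_count), n)
  if (any(!is.na(particle_count) & particle_count <= 0)) {
    stop("particle counts must be positive", call. = FALSE)
  }
  out <- data.frame(bin = seq_len(n),
                    mass_fraction = as.numeric(mass_fraction),
                    mean_diameter_um = as.numeric(mean_diameter_um),
                    lag_time_h = lag_time_h,
                    particle_count = particle_count)
  attr(out, "cut_fractions") <- cut_fractions
  class(out) <- c("size_bin_set", "data.frame")
  out
}

#' @export
print.size_bin_set <- function(x, ...) {
  cat(sprintf("size_bin_set: %d bins, diameters %.3g-%.3g um\n",
              nrow(x), min(x$mean_diameter_um), max(x$mean_diameter_um)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Set per-bin lag times on a bin set
#'
#' @param bins a `size_bin_set`.
#' @param lag_time_h lag times in hours, one per bin.
#' @return the updated `size_bin_set`.
#' @export
set_lag_times <- function(bins, lag_time_h) {
  stopifnot(inherits(bins, "size_bin_set"))
  if (length(lag_time_h) != nrow(bins)) {
    stop("need one lag time per bin", call. = FALSE)
  }
  if (any(lag_time_h < 0)) stop("lag times must be >= 0", call. = FALSE)
  bins$lag_time_h <- as.numeric(lag_time_h)
  bins
}

# inverse of the piecewise-linear cumulative curve: diameter at mass quantile q
.psd_quantile <- function(psd, q) {
  x <- psd$cum_mass_fraction
  d <- psd$diameter_um
  # prepend an implicit zero-mass origin if the curve starts above 0
  if (x[1] > 0) {
    x <- c(0, x)
    d <- c(d[1], d)
  }
  stats::approx(x, d, xout = q, ties = "ordered", rule = 2)$y
}

# exact integral of the piecewise-linear quantile function d(F) over [a, b],
# used for mass-weighted mean diameters
.psd_mean_diameter <- function(psd, a, b) {
  x <- psd$cum_mass_fraction
  d <- psd$diameter_um
  if (x[1] > 0) {
    x <- c(0, x)
    d <- c(d[1], d)
  }
  knots <- sort(unique(c(a, b, x[x > a & x < b])))
  dk <- stats::approx(x, d, xout = knots, ties = "ordered", rule = 2)$y
  # trapezoid is exact for a piecewise-linear integrand with knots included
  area <- sum(diff(knots) * (utils::head(dk, -1) + utils::tail(dk, -1)) / 2)
  area / (b - a)
}

#' Bin a particle-size distribution into mass-percentile size classes
#'
#' Splits the cumulative mass curve at the given cutpoints and computes one
#' representative diameter per bin. The default representative value is the
#' mass-weighted mean diameter over the bin's mass interval, computed by
#' linear interpolation of the cumulative curve in (diameter, cumulative
#' fraction) space; since bins are mass percentiles this is the natural
#' average. `"median"` takes the diameter at the bin's mass midpoint and
#' `"geometric"` the geometric mean of the bin's edge diameters.
#'
#' @param psd a `psd` object (see [particle_size_distribution()]).
#' @param cuts strictly increasing cumulative-mass cutpoints from 0 to 1.
#' @param method representative-diameter rule: `"mass_weighted"` (default),
#'   `"median"` or `"geometric"`.
#' @return a `size_bin_set` with `mass_fraction = diff(cuts)` and per-bin
#'   mean diameters.
#' @examples
#' psd <- particle_size_distribution(c(1, 2), c(0.5, 1))
#' bin_psd(psd, cuts = c(0, 0.5, 1))
#' @export
bin_psd <- function(psd, cuts = default_cut_fractions(),
                    method = c("mass_weighted", "median", "geometric")) {
  if (!inherits(psd, "psd")) {
    psd <- particle_size_distribution(psd$diameter_um, psd$cum_mass_fraction)
  }
  method <- match.arg(method)
  cuts <- as.numeric(cuts)
  if (length(cuts) < 2 || any(diff(cuts) <= 0) ||
      abs(cuts[1]) > 1e-12 || abs(cuts[length(cuts)] - 1) > 1e-12) {
    stop("cuts must increase strictly from 0 to 1", call. = FALSE)
  }
  lo <- utils::head(cuts, -1)
  hi <- utils::tail(cuts, -1)
  dmean <- switch(method,
    mass_weighted = vapply(seq_along(lo), function(i)
      .psd_mean_diameter(psd, lo[i], hi[i]), numeric(1)),
    median = .psd_quantile(psd, (lo + hi) / 2),
    geometric = sqrt(.psd_quantile(psd, lo) * .psd_quantile(psd, hi))
  )
  # monotone by construction up to numerical noise; enforce exactly
  dmean <- cummax(dmean)
  size_bin_set(mass_fraction = hi - lo, mean_diameter_um = dmean,
               cut_fractions = cuts)
}

#' Allocate particle counts to size bins for a given dose
#'
#' Each bin holds `f_n * F * dose` milligrams of solid, carried by
#' `N_n = f_n * F * dose / ((pi/6) * rho * d_n^3)` identical spheres of the
#' bin's mean diameter. The systemic bioavailability `F` scales the depot
#' load so that all dissolved drug reaching the central compartment
#' integrates to `F * dose`.
#'
#' @param bins a `size_bin_set`.
#' @param dose_mg administered dose in milligrams of active moiety.
#' @param bioavailability fraction of the dose available to the depot, in
#'   `(0, 1]`.
#' @param density_g_cm3 solid density in g/cm^3.
#' @return the `size_bin_set` with `particle_count` filled in and the
#'   initial per-bin solid masses attached as attribute `solid0_mg`.
#' @export
assign_particle_counts <- function(bins, dose_mg, bioavailability = 1,
                                   density_g_cm3) {
  stopifnot(inherits(bins, "size_bin_set"))
  if (dose_mg <= 0) stop("dose must be positive", call. = FALSE)
  if (bioavailability <= 0 || bioavailability > 1) {
    stop("bioavailability must be in (0, 1]", call. = FALSE)
  }
  if (density_g_cm3 <= 0) stop("density must be positive", call. = FALSE)
  if (any(bins$mean_diameter_um <= 0)) stop("zero bin diameter", call. = FALSE)
  d_cm <- convert_unit(bins$mean_diameter_um, "um", "cm")
  rho_mg_ml <- convert_unit(density_g_cm3, "g/cm^3", "mg/mL")
  solid0 <- bins$mass_fraction * bioavailability * dose_mg
  single_mass <- (pi / 6) * rho_mg_ml * d_cm^3            # mg per sphere
  bins$particle_count <- solid0 / single_mass
  attr(bins, "solid0_mg") <- solid0
  bins
}

#' Write a bin set to CSV
#'
#' Header `bin,mass_fraction,mean_diameter_um,lag_time_h,particle_count`.
#'
#' @param bins a `size_bin_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bins_csv <- function(bins, path) {
  stopifnot(inherits(bins, "size_bin_set"))
  utils::write.csv(as.data.frame(bins), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bin set from CSV
#'
#' @param path path written by [write_bins_csv()].
#' @return a `size_bin_set`.
#' @export
read_bins_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mass_fraction", "mean_diameter_um")
  if (!all(need %in% names(df))) {
    stop("bin file must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  size_bin_set(df$mass_fraction, df$mean_diameter_um,
               lag_time_h = if ("lag_time_h" %in% names(df)) df$lag_time_h else NA_real_,
               particle_count = if ("particle_count" %in% names(df)) df$particle_count else NA_real_)
}
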