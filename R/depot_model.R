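#' Current particle radius of a size bin
#'
#' Each bin is modelled as `N_n` identical shrinking spheres; the radius is
#' recovered from the remaining per-particle mass,
#' `r = (3 * (Solid_n / N_n) / (4 * pi * rho))^(1/3)`. A fully dissolved bin
#' (zero solid mass) has radius 0.
#'
#' @param solid_mass_mg remaining solid mass of the bin, mg.
#' @param particle_count number of particles in the bin.
#' @param density_g_cm3 solid density, g/cm^3.
#' @return particle radius in micrometres.
#' @examples
#' # a bin of one 1-um-radius sphere
#' rho <- 1.2
#' m <- 4 / 3 * pi * (1e-4)^3 * rho * 1000 # mg
#' bin_radius(m, 1, rho)
#' @export
bin_radius <- function(solid_mass_mg, particle_count, density_g_cm3) {
  if (any(particle_count <= 0) || any(density_g_cm3 <= 0)) {
    stop("particle count and density must be positive", call. = FALSE)
  }
  if (any(solid_mass_mg < 0)) stop("solid mass must be >= 0", call. = FALSE)
  rho <- convert_unit(density_g_cm3, "g/cm^3", "mg/mL")
  r_cm <- (3 * (solid_mass_mg / particle_count) / (4 * pi * rho))^(1 / 3)
  convert_unit(r_cm, "cm", "um")
}

# pack canonical parameters into the fixed-layout vector expected by the
# compiled RHS (src/depot_rhs.c); MAXBINS there is 64
.pack_parms <- function(p) {
  maxbins <- 64L
  if (p$n_bins > maxbins) stop("at most 64 size bins are supported", call. = FALSE)
  lag <- numeric(maxbins)
  npart <- numeric(maxbins)
  lag[seq_len(p$n_bins)] <- p$lag
  npart[seq_len(p$n_bins)] <- p$n_particles
  c(p$n_bins, p$S, p$rho, p$D, p$h, p$v_region, p$cl_perf, p$ke, lag, npart)
}

# core right-hand side in canonical units (mg, mL, cm, h); reference R
# implementation of the compiled RHS, used by state_derivative()
# state: [solids 1..n, regional, central, eliminated]
.depot_rhs <- function(t, y, p) {
  n <- p$n_bins
  solids <- pmax(y[seq_len(n)], 0)
  regional <- y[n + 1]
  central <- y[n + 2]
  c_reg <- regional / p$v_region
  r <- ifelse(solids > 0, (3 * (solids / p$n_particles) / (4 * pi * p$rho))^(1 / 3), 0)
  # Nernst-Brunner film dissolution of N identical spheres, gated by lag
  # time; the rate is clamped at <= 0 (dissolution only, no regrowth)
  rate <- ifelse(t <= p$lag | solids <= 0, 0,
                 pmin(0, -p$n_particles * (p$D / p$h) * 4 * pi * r * (r + p$h) *
                        (p$S - c_reg)))
  d_regional <- -sum(rate) - c_reg * p$cl_perf
  d_central <- c_reg * p$cl_perf - central * p$ke
  list(c(rate, d_regional, d_central, central * p$ke))
}

#' Time derivative of the depot state
#'
#' Evaluates the model right-hand side at one time point: per-bin
#' diffusion-layer dissolution gated by lag times, the regional dissolved
#' mass balance, first-order transfer to the central compartment and
#' first-order elimination. The four groups of components sum to zero
#' (closed mass balance); the eliminated-mass component is bookkeeping that
#' makes the conservation explicit.
#'
#' @param t time, hours.
#' @param state named list or vector with elements `solid_mass` (per-bin,
#'   mg), `regional_dissolved` (mg), `central_mass` (mg) and optionally
#'   `eliminated_mass` (mg).
#' @param spec a `depot_model_spec`.
#' @return named list of derivatives (mg/h): `solid_mass`,
#'   `regional_dissolved`, `central_mass`, `eliminated_mass`.
#' @export
state_derivative <- function(t, state, spec) {
  p <- unit_normalize(spec)
  solids <- state$solid_mass
  if (length(solids) != p$n_bins) stop("need one solid mass per bin", call. = FALSE)
  y <- c(solids, state$regional_dissolved, state$central_mass,
         state$eliminated_mass %||% 0)
  if (any(y < 0)) stop("state components must be >= 0", call. = FALSE)
  d <- .depot_rhs(t, y, p)[[1]]
  n <- p$n_bins
  list(solid_mass = d[seq_len(n)],
       regional_dissolved = d[n + 1],
       central_mass = d[n + 2],
       eliminated_mass = d[n + 3])
}

#' Default output grid for depot simulations
#'
#' 0.1 h spacing over the first day (to resolve an early peak), then 1 h.
#'
#' @param t_end_h simulation horizon, hours.
#' @return numeric vector of output times from 0 to `t_end_h`.
#' @export
default_output_times <- function(t_end_h) {
  fine <- seq(0, min(24, t_end_h), by = 0.1)
  if (t_end_h <= 24) return(round(fine, 8))
  sort(unique(round(c(fine, seq(24, t_end_h, by = 1), t_end_h), 8)))
}

#' Simulate a depot-model specification forward in time
#'
#' Integrates the per-bin dissolution / regional / central mass balance from
#' an undissolved depot (`Solid_n(0) = f_n * F * dose`, everything else 0)
#' with a stiff adaptive solver ([deSolve::lsoda]). Because each lag time is
#' a derivative discontinuity, integration is restarted at every distinct
#' lag time. The perfusion rate constant `CL_perf / V_region` can exceed
#' 1e4 / h, which is what makes the system stiff.
#'
#' @param spec a `depot_model_spec`.
#' @param t_end_h simulation horizon, hours.
#' @param output_times optional explicit output grid (hours, starting at 0);
#'   defaults to [default_output_times()].
#' @param rtol,atol solver tolerances (defaults 1e-8 and 1e-12 mg).
#' @return a `depot_sim` object: list with `time_h`; `plasma` (data frame
#'   `time_h`, `conc_ng_ml`); `regional_conc` (data frame `time_h`,
#'   `conc_mg_ml` of dissolved drug in the depot); `solids` (matrix of
#'   per-bin solid masses in mg, one column per bin); `state` (full state
#'   matrix, mg) and the spec.
#' @examples
#' \donttest{
#' sim <- simulate_depot(example_spec("human_R"), t_end_h = 2880)
#' max(sim$plasma$conc_ng_ml)
#' }
#' @export
simulate_depot <- function(spec, t_end_h, output_times = NULL,
                           rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(spec, "depot_model_spec"))
  if (t_end_h <= 0) stop("t_end_h must be positive", call. = FALSE)
  p <- unit_normalize(spec)
  times <- if (is.null(output_times)) default_output_times(t_end_h) else {
    ot <- sort(unique(round(as.numeric(output_times), 8)))
    if (ot[1] > 0) ot <- c(0, ot)
    ot
  }
  if (max(times) > t_end_h + 1e-6) stop("output times exceed t_end_h", call. = FALSE)
  times[times > t_end_h] <- t_end_h
  times <- unique(times)

  n <- p$n_bins
  packed <- .pack_parms(p)
  y0 <- c(p$solid0, 0, 0, 0)
  if (p$amount == 0 || spec$dose_mg == 0) {
    state <- matrix(rep(y0, each = length(times)), nrow = length(times))
  } else {
    breaks <- sort(unique(p$lag))
    breaks <- breaks[breaks > 0 & breaks < max(times)]
    # merge breakpoints closer than the solver can separate
    if (length(breaks) > 1) breaks <- breaks[c(TRUE, diff(breaks) > 1e-6)]
    seg_ends <- unique(c(breaks, max(times)))
    state <- matrix(NA_real_, nrow = length(times), ncol = n + 3)
    state[1, ] <- y0
    t0 <- 0
    for (t1 in seg_ends) {
      tt <- sort(unique(c(t0, times[times > t0 + 1e-9 & times < t1 - 1e-9], t1)))
      out <- try(deSolve::lsoda(y0, tt, func = "depot_derivs", parms = packed,
                                dllname = "laidepot", initfunc = "depot_initmod",
                                rtol = rtol, atol = atol, maxsteps = 50000),
                 silent = TRUE)
      if (inherits(out, "try-error") || nrow(out) < length(tt)) {
        stop(sprintf("depot ODE integration failed in segment [%g, %g] h", t0, t1),
             call. = FALSE)
      }
      keep <- match(round(times[times > t0 + 1e-9 & times <= t1 + 1e-9], 8),
                    round(out[, 1], 8))
      rows <- which(times > t0 + 1e-9 & times <= t1 + 1e-9)
      state[rows, ] <- out[keep, -1, drop = FALSE]
      y0 <- out[nrow(out), -1]
      # freeze numerically exhausted bins, clamp tiny negatives
      y0[seq_len(n)][y0[seq_len(n)] < 1e-12] <- 0
      y0 <- pmax(y0, 0)
      t0 <- t1
    }
    state[state < 0 & state > -1e-9] <- 0
  }
  vd_ml <- p$vd
  plasma <- data.frame(time_h = times,
                       conc_ng_ml = state[, n + 2] / vd_ml * 1e6)
  regional <- data.frame(time_h = times,
                         conc_mg_ml = state[, n + 1] / p$v_region)
  structure(list(time_h = times, plasma = plasma, regional_conc = regional,
                 solids = state[, seq_len(n), drop = FALSE],
                 state = state, spec = spec, amount_mg = p$amount),
            class = "depot_sim")
}

#' @export
print.depot_sim <- function(x, ...) {
  cmax <- max(x$plasma$conc_ng_ml)
  tmax <- x$plasma$time_h[which.max(x$plasma$conc_ng_ml)]
  cat(sprintf("depot_sim '%s': %d time points to %g h\n", x$spec$name,
              length(x$time_h), max(x$time_h)))
  cat(sprintf("  Cmax %.4g ng/mL at %g h | trapezoidal AUC0-t %.6g ng*h/mL\n",
              cmax, tmax, auc_trapz(x$plasma$time_h, x$plasma$conc_ng_ml)))
  invisible(x)
}

#' @export
plot.depot_sim <- function(x, which = c("plasma", "regional", "solids"), ...) {
  which <- match.arg(which)
  if (which == "plasma") {
    graphics::plot(x$plasma$time_h / 24, x$plasma$conc_ng_ml, type = "l",
                   xlab = "time (days)", ylab = "plasma concentration (ng/mL)", ...)
  } else if (which == "regional") {
    graphics::plot(x$regional_conc$time_h / 24, x$regional_conc$conc_mg_ml,
                   type = "l", xlab = "time (days)",
                   ylab = "dissolved depot concentration (mg/mL)", ...)
  } else {
    graphics::matplot(x$time_h / 24, x$solids, type = "l", lty = 1,
                      xlab = "time (days)", ylab = "per-bin solid mass (mg)", ...)
  }
  invisible(x)
}

#' Trapezoidal area under a curve
#'
#' Linear trapezoid on the sampled points; exact for piecewise-linear
#' curves.
#'
#' @param time x values, strictly increasing.
#' @param conc y values.
#' @return the integral.
#' @export
auc_trapz <- function(time, conc) {
  if (length(time) != length(conc)) stop("lengths differ", call. = FALSE)
  if (length(time) < 2) return(0)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  sum(diff(time) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
}

#' Simulate until the plasma curve has decayed away
#'
#' Repeatedly extends the horizon (doubling) until the terminal plasma
#' concentration falls below `c_stop`, so that the trapezoidal area is an
#' effectively complete AUC. Used for the mass-transit identity
#' `AUC0-inf = F * dose / (Vd * ke)`.
#'
#' @param spec a `depot_model_spec`.
#' @param t_start_h initial horizon guess, hours.
#' @param c_stop stopping plasma concentration, ng/mL (default 1e-6).
#' @param max_doublings safety cap on extensions.
#' @param coarse logical; use a coarse (faster) output grid.
#' @return a `depot_sim`.
#' @export
simulate_to_completion <- function(spec, t_start_h = NULL, c_stop = 1e-6,
                                   max_doublings = 12, coarse = TRUE) {
  p <- unit_normalize(spec)
  if (is.null(t_start_h)) {
    # crude horizon: lag + transfer-limited release time + elimination tail
    release <- p$amount / (p$S * p$cl_perf)
    t_start_h <- max(p$lag) + 2 * release + 30 / p$ke + 24
  }
  t_end <- t_start_h
  for (i in seq_len(max_doublings)) {
    grid <- if (coarse) {
      sort(unique(round(c(seq(0, min(48, t_end), by = 0.25),
                          seq(0, t_end, length.out = 2000), t_end), 8)))
    } else NULL
    sim <- simulate_depot(spec, t_end, output_times = grid)
    if (utils::tail(sim$plasma$conc_ng_ml, 1) < c_stop) return(sim)
    t_end <- t_end * 2
  }
  warning("plasma concentration did not fall below c_stop; returning longest run")
  sim
}
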