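#' Construct a concentration-time series
#'
#' The universal exchange type between the simulator, the NCA and the
#' fitting layer: strictly increasing times in hours, non-negative plasma
#' concentrations in ng/mL.
#'
#' @param time_h times, hours.
#' @param conc_ng_ml concentrations, ng/mL.
#' @param blq optional logical flags marking below-quantification values
#'   (stored as zero concentration).
#' @return a `conc_series` data frame.
#' @export
conc_series <- function(time_h, conc_ng_ml, blq = NULL) {
  if (length(time_h) != length(conc_ng_ml)) {
    stop("time and concentration vectors must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time_h))) stop("times must be finite", call. = FALSE)
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(conc_ng_ml)) || any(conc_ng_ml < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  out <- data.frame(time_h = as.numeric(time_h),
                    conc_ng_ml = as.numeric(conc_ng_ml))
  out$blq <- if (is.null(blq)) rep(FALSE, nrow(out)) else as.logical(blq)
  class(out) <- c("conc_series", "data.frame")
  out
}

# choose indices of the terminal log-linear phase
.terminal_indices <- function(time, conc, terminal, lloq, tmax_idx) {
  usable <- which(conc > 0 & conc >= lloq & seq_along(conc) >= tmax_idx)
  if (length(usable) < 3) {
    usable <- which(conc > 0 & conc >= lloq) # fall back: ignore Tmax guard
  }
  if (length(usable) < 3) return(NULL)
  if (identical(terminal, "auto")) {
    # best adjusted-R^2 over the last 3..8 usable points
    best <- NULL
    best_r2 <- -Inf
    for (k in 3:min(8, length(usable))) {
      idx <- utils::tail(usable, k)
      fitl <- stats::lm(log(conc[idx]) ~ time[idx])
      r2 <- suppressWarnings(summary(fitl)$adj.r.squared)
      if (is.finite(r2) && r2 > best_r2) {
        best_r2 <- r2
        best <- idx
      }
    }
    best
  } else {
    k <- as.integer(terminal)
    if (is.na(k) || k < 3) stop("need at least 3 terminal points", call. = FALSE)
    if (k > length(usable)) k <- length(usable)
    utils::tail(usable, k)
  }
}

#' Non-compartmental analysis of a concentration-time curve
#'
#' Model-free pharmacokinetic summary: Cmax and Tmax are read directly from
#' the observations (earliest time on ties); AUC0-t by the linear trapezoid;
#' the terminal elimination rate constant `ke` by least-squares regression
#' of `log(C)` on time over the chosen terminal points;
#' `AUC0-inf = AUC0-t + C_t / ke`; `t1/2 = 0.693 / ke`; AUMC by trapezoid on
#' `t * C` plus the tail `C_t * t_last / ke + C_t / ke^2`; and
#' `MRT = AUMC0-inf / AUC0-inf`.
#'
#' Values below the lower limit of quantification are excluded from the
#' terminal regression (zeros before Tmax are retained for the AUC). When
#' the fitted terminal slope is non-negative, `ke` and all extrapolated
#' quantities are returned as `NA` and `extrapolation_valid` is `FALSE`.
#'
#' @param series a `conc_series` (or data frame with `time_h`,
#'   `conc_ng_ml`).
#' @param terminal number of terminal points for the log-linear regression
#'   (default 3, the last quantifiable points), or `"auto"` to pick the
#'   best adjusted-R^2 window over the last 3..8 points.
#' @param lloq lower limit of quantification, ng/mL (default 0.5).
#' @return an `nca_result` list: `cmax`, `tmax`, `auc_0_t`, `auc_0_inf`,
#'   `ke`, `t_half`, `aumc_0_inf`, `mrt`, `n_terminal_points`,
#'   `extrapolation_valid`.
#' @examples
#' t <- 0:48
#' nca <- run_nca(conc_series(t, 100 * exp(-0.1 * t)))
#' nca$t_half
#' @export
run_nca <- function(series, terminal = 3, lloq = 0.5) {
  if (!inherits(series, "conc_series")) {
    series <- conc_series(series$time_h, series$conc_ng_ml)
  }
  time <- series$time_h
  conc <- series$conc_ng_ml
  if (sum(conc > 0) < 3) {
    stop("need at least 3 positive concentrations for NCA", call. = FALSE)
  }
  tmax_idx <- which.max(conc) # which.max takes the earliest tie
  cmax <- conc[tmax_idx]
  tmax <- time[tmax_idx]
  auc_t <- auc_trapz(time, conc)
  aumc_t <- auc_trapz(time, time * conc)
  idx <- .terminal_indices(time, conc, terminal, lloq, tmax_idx)
  ke <- NA_real_
  n_term <- 0L
  if (!is.null(idx)) {
    slope <- stats::coef(stats::lm(log(conc[idx]) ~ time[idx]))[2]
    n_term <- length(idx)
    if (is.finite(slope) && slope < 0) ke <- -as.numeric(slope)
  }
  ok <- is.finite(ke)
  c_last <- conc[max(which(conc > 0))]
  t_last <- time[max(which(conc > 0))]
  out <- list(
    cmax = cmax, tmax = tmax,
    auc_0_t = auc_t,
    auc_0_inf = if (ok) auc_t + c_last / ke else NA_real_,
    ke = ke,
    t_half = if (ok) 0.693 / ke else NA_real_,
    aumc_0_inf = if (ok) aumc_t + c_last * t_last / ke + c_last / ke^2 else NA_real_,
    mrt = NA_real_,
    n_terminal_points = n_term,
    extrapolation_valid = ok)
  if (ok) out$mrt <- out$aumc_0_inf / out$auc_0_inf
  class(out) <- "nca_result"
  out
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Non-compartmental analysis\n")
  cat(sprintf("  Cmax %.4g ng/mL at Tmax %g h\n", x$cmax, x$tmax))
  cat(sprintf("  AUC0-t %.6g ng*h/mL | AUC0-inf %.6g ng*h/mL\n",
              x$auc_0_t, x$auc_0_inf))
  cat(sprintf("  ke %.4g 1/h (%d terminal points) | t1/2 %.4g h | MRT %.4g h\n",
              x$ke, x$n_terminal_points, x$t_half, x$mrt))
  if (!x$extrapolation_valid) {
    cat("  terminal slope not negative: extrapolated fields are NA\n")
  }
  invisible(x)
}
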