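#' Two-point Stern-Volmer calibration of the oxygen sensor
#'
#' The luminescence of the ruthenium dye RTDP is dynamically quenched by
#' dissolved oxygen following the Stern-Volmer relation
#' \deqn{[O_2] = \frac{1}{K_q}\left(\frac{\tau_0}{\tau} - 1\right)}
#' where \eqn{\tau_0} is the lifetime at 0% oxygen and \eqn{K_q} the
#' quenching constant. Calibrating at 0% oxygen (giving `tau0_ns`) and at one
#' oxic point (giving `tau_ox_ns` at `o2_ox_fraction` of full scale) fixes
#' \eqn{K_q = (\tau_0/\tau_{ox} - 1) / [O_2]_{ox}}.
#'
#' Oxygen is expressed internally as a fraction of the full calibration
#' scale (1.0 = 100%); `Kq` is then dimensionless. Lifetimes are temperature
#' dependent, so a calibration carries its temperature label and must not be
#' mixed with traces measured at another temperature.
#'
#' @param tau0_ns lifetime at 0% oxygen (ns).
#' @param tau_ox_ns lifetime at the oxic calibration point (ns); must be
#'   smaller than `tau0_ns`.
#' @param o2_ox_fraction oxygen at the oxic point as a fraction of full
#'   scale (default 1.0, i.e. calibrated at 100%).
#' @param temperature_c calibration temperature in degrees Celsius.
#' @return object of class `stern_volmer_calibration` with fields
#'   `tau0_ns`, `tau_ox_ns`, `o2_ox_fraction`, `temperature_c`, `kq`.
#' @examples
#' fit_stern_volmer(526, 144, 1.0, 30)   # Kq = 2.65
#' @export
fit_stern_volmer <- function(tau0_ns, tau_ox_ns, o2_ox_fraction = 1.0,
                             temperature_c = NA_real_) {
  if (!(tau_ox_ns > 0)) stop("tau_ox_ns must be > 0")
  if (!(tau0_ns > tau_ox_ns))
    stop("tau0_ns must exceed tau_ox_ns (no quenching otherwise; ",
         "the Stern-Volmer inversion is undefined)")
  if (o2_ox_fraction <= 0 || o2_ox_fraction > 1)
    stop("o2_ox_fraction must lie in (0, 1]")
  structure(
    list(tau0_ns = tau0_ns, tau_ox_ns = tau_ox_ns,
         o2_ox_fraction = o2_ox_fraction, temperature_c = temperature_c,
         kq = (tau0_ns / tau_ox_ns - 1) / o2_ox_fraction),
    class = "stern_volmer_calibration")
}

#' @export
print.stern_volmer_calibration <- function(x, ...) {
  cat(sprintf("<stern_volmer_calibration> tau0 = %g ns, tau_ox = %g ns at %g%% O2, T = %g degC -> Kq = %.4f\n",
              x$tau0_ns, x$tau_ox_ns, 100 * x$o2_ox_fraction,
              x$temperature_c, x$kq))
  invisible(x)
}

#' Oxygen concentration from a measured lifetime
#'
#' Inverts the Stern-Volmer relation:
#' \eqn{[O_2] = (1/K_q)(\tau_0/\tau - 1)}, in fractions of full scale.
#' Noisy lifetimes may give slightly negative or super-unity readings; these
#' are deliberately not clipped (clipping would bias downstream averages).
#'
#' @param tau_ns measured lifetime(s), ns; must be > 0.
#' @param calib a [fit_stern_volmer()] calibration.
#' @return oxygen as a fraction of full scale (same length as `tau_ns`).
#' @export
o2_from_lifetime <- function(tau_ns, calib) {
  stopifnot(inherits(calib, "stern_volmer_calibration"))
  if (any(!is.finite(tau_ns) | tau_ns <= 0))
    stop("tau_ns must be finite and > 0")
  (calib$tau0_ns / tau_ns - 1) / calib$kq
}

#' Lifetime expected at a given oxygen concentration
#'
#' Forward Stern-Volmer model, \eqn{\tau = \tau_0 / (1 + K_q [O_2])}; used by
#' the synthetic FLIM generator.
#'
#' @param o2_fraction oxygen as a fraction of full scale (>= 0).
#' @param calib a [fit_stern_volmer()] calibration.
#' @return lifetime(s) in ns.
#' @export
lifetime_from_o2 <- function(o2_fraction, calib) {
  stopifnot(inherits(calib, "stern_volmer_calibration"))
  if (any(o2_fraction < 0)) stop("o2_fraction must be >= 0")
  calib$tau0_ns / (1 + calib$kq * o2_fraction)
}

#' Oxygen concentration time series
#'
#' @param times_s strictly increasing sample times (s).
#' @param o2_fraction concentration per sample, fraction of full scale
#'   (values may transiently leave `[0, 1]` under noise).
#' @param source_roi label of the imaging ROI the trace was derived from.
#' @param temperature_c temperature label carried from the calibration.
#' @return object of class `o2_trace`.
#' @export
o2_trace <- function(times_s, o2_fraction, source_roi = "",
                     temperature_c = NA_real_) {
  if (length(times_s) != length(o2_fraction))
    stop("times_s and o2_fraction must have equal length")
  if (length(times_s) > 1 && any(diff(times_s) <= 0))
    stop("times_s must be strictly increasing")
  structure(list(times_s = as.numeric(times_s),
                 o2_fraction = as.numeric(o2_fraction),
                 source_roi = source_roi, temperature_c = temperature_c),
            class = "o2_trace")
}

#' @export
print.o2_trace <- function(x, ...) {
  n <- length(x$times_s)
  cat(sprintf("<o2_trace> %d samples over %.2f h%s\n", n,
              if (n) diff(range(x$times_s)) / 3600 else 0,
              if (nzchar(x$source_roi)) paste0(" (", x$source_roi, ")") else ""))
  invisible(x)
}

#' Convert a mean-lifetime series to an oxygen trace
#'
#' Element-wise Stern-Volmer inversion of a series of ROI-mean lifetimes.
#' Non-positive or non-finite lifetimes propagate as `NA` with a warning
#' giving the count. If `temperature_c` is supplied and differs from the
#' calibration's temperature label, conversion is refused: the sensor
#' lifetime is temperature dependent, so calibration and measurement must
#' share a temperature.
#'
#' @param times_s strictly increasing sample times (s).
#' @param tau_ns mean lifetime per sample (ns).
#' @param calib a [fit_stern_volmer()] calibration.
#' @param source_roi ROI label carried into the trace.
#' @param temperature_c temperature at which the lifetimes were measured.
#' @return an [o2_trace()].
#' @export
trace_from_lifetimes <- function(times_s, tau_ns, calib, source_roi = "",
                                 temperature_c = NULL) {
  stopifnot(inherits(calib, "stern_volmer_calibration"))
  if (!is.null(temperature_c) && !is.na(calib$temperature_c) &&
      !isTRUE(all.equal(temperature_c, calib$temperature_c)))
    stop(sprintf("temperature mismatch: lifetimes at %g degC, calibration at %g degC",
                 temperature_c, calib$temperature_c))
  bad <- !is.finite(tau_ns) | tau_ns <= 0
  o2 <- rep(NA_real_, length(tau_ns))
  if (any(!bad)) o2[!bad] <- o2_from_lifetime(tau_ns[!bad], calib)
  if (any(bad))
    warning(sum(bad), " sample(s) had undefined lifetime; set to NA")
  o2_trace(times_s, o2, source_roi = source_roi,
           temperature_c = calib$temperature_c)
}

#' Programmed oxygen step schedule
#'
#' @param levels_percent ordered gas-phase setpoints in % oxygen (0-100).
#' @param initial_hold_h duration of the first level (h).
#' @param step_duration_h duration of each subsequent level (h).
#' @param sample_interval_min imaging period (min).
#' @return object of class `step_schedule`.
#' @export
step_schedule <- function(levels_percent, initial_hold_h = 4,
                          step_duration_h = 3, sample_interval_min = 5) {
  if (any(levels_percent < 0 | levels_percent > 100))
    stop("levels must lie within [0, 100] %")
  if (initial_hold_h <= 0 || step_duration_h <= 0 || sample_interval_min <= 0)
    stop("durations and sampling interval must be > 0")
  structure(list(levels_percent = as.numeric(levels_percent),
                 initial_hold_h = initial_hold_h,
                 step_duration_h = step_duration_h,
                 sample_interval_min = sample_interval_min),
            class = "step_schedule")
}

#' Default step-test schedule
#'
#' The standard characterization program: 0, 2, 4, 6, 8, 10, 15, 21 and
#' finally 100% oxygen; the initial anoxic phase is held 4 h, every later
#' level 3 h (30 h in total), sampled every 5 min.
#' @return a [step_schedule()].
#' @export
default_step_schedule <- function() {
  step_schedule(c(0, 2, 4, 6, 8, 10, 15, 21, 100),
                initial_hold_h = 4, step_duration_h = 3,
                sample_interval_min = 5)
}

#' @export
print.step_schedule <- function(x, ...) {
  cat(sprintf("<step_schedule> %s %% O2; first level %g h, others %g h, sampled every %g min (total %g h)\n",
              paste(x$levels_percent, collapse = ", "), x$initial_hold_h,
              x$step_duration_h, x$sample_interval_min,
              x$initial_hold_h + (length(x$levels_percent) - 1) * x$step_duration_h))
  invisible(x)
}

# per-step [start, end) boundaries in seconds
schedule_boundaries <- function(schedule) {
  n <- length(schedule$levels_percent)
  starts_h <- c(0, schedule$initial_hold_h +
                  (seq_len(n - 1) - 1) * schedule$step_duration_h)
  durs_h <- c(schedule$initial_hold_h, rep(schedule$step_duration_h, n - 1))
  data.frame(step = seq_len(n), setpoint_percent = schedule$levels_percent,
             start_s = starts_h * 3600, end_s = (starts_h + durs_h) * 3600)
}

#' Per-step plateau concentrations
#'
#' The concentration reached in each step is estimated by averaging the
#' measured trace over the final `window_min` minutes of the step (default:
#' the last hour, where the first-order chip response has essentially
#' equilibrated). Samples are attributed to steps by half-open intervals
#' `[step start, step end)`.
#'
#' @param trace an [o2_trace()].
#' @param schedule the [step_schedule()] that produced the trace.
#' @param window_min averaging window at the end of each step (min).
#' @return data.frame (class `plateau_summary`): `step`, `setpoint_percent`,
#'   `plateau_fraction`, `n_samples`.
#' @export
plateau_values <- function(trace, schedule, window_min = 60) {
  stopifnot(inherits(trace, "o2_trace"), inherits(schedule, "step_schedule"))
  b <- schedule_boundaries(schedule)
  if (max(trace$times_s) < max(b$start_s))
    stop("trace does not span the schedule")
  out <- b[c("step", "setpoint_percent")]
  out$plateau_fraction <- NA_real_
  out$n_samples <- 0L
  for (i in seq_len(nrow(b))) {
    if (b$end_s[i] - b$start_s[i] < window_min * 60) {
      warning(sprintf("step %d is shorter than the %g min averaging window; truncated",
                      i, window_min))
      w0 <- b$start_s[i]
    } else w0 <- b$end_s[i] - window_min * 60
    sel <- trace$times_s >= w0 & trace$times_s < b$end_s[i]
    # the very last schedule sample (t == end of final step) still belongs
    # to the final step
    if (i == nrow(b)) sel <- sel | trace$times_s == b$end_s[i]
    v <- trace$o2_fraction[sel]
    v <- v[is.finite(v)]
    out$plateau_fraction[i] <- if (length(v)) mean(v) else NA_real_
    out$n_samples[i] <- length(v)
  }
  class(out) <- c("plateau_summary", "data.frame")
  out
}

#' Switching times of the chip response
#'
#' For each step the initial value `c_i` is the last sample before step
#' onset (for the first step: the first sample of the trace) and the final
#' value `c_f` is the plateau mean from [plateau_values()]. The switching
#' time \eqn{t_X} is the first time after onset at which the trace crosses
#' `c_i + X * (c_f - c_i)` toward `c_f` - by default the crossing must be
#' sustained for the remainder of the step (robust against noise spikes);
#' set `sustained = FALSE` for the pure first crossing. Crossings are
#' located by linear interpolation between samples. A step with
#' `c_f == c_i` is degenerate: all times are 0 and flagged.
#'
#' @param trace an [o2_trace()].
#' @param schedule the driving [step_schedule()].
#' @param thresholds fractions of the step change (default 0.85, 0.90, 0.95).
#' @param sustained require the trace to stay beyond the threshold for the
#'   rest of the step (default `TRUE`).
#' @param plateaus optional precomputed [plateau_values()] result.
#' @return data.frame (class `switching_times`): per step the setpoint,
#'   plateau, one `t<XX>_min` column per threshold (minutes after onset,
#'   `NA` when never reached), and a `degenerate` flag.
#' @export
switching_times <- function(trace, schedule,
                            thresholds = c(0.85, 0.90, 0.95),
                            sustained = TRUE, plateaus = NULL) {
  stopifnot(inherits(trace, "o2_trace"), inherits(schedule, "step_schedule"))
  thresholds <- sort(thresholds)
  if (is.null(plateaus)) plateaus <- plateau_values(trace, schedule)
  b <- schedule_boundaries(schedule)
  tcol <- sprintf("t%d_min", round(100 * thresholds))
  out <- b[c("step", "setpoint_percent")]
  out$plateau_fraction <- plateaus$plateau_fraction
  for (nm in tcol) out[[nm]] <- NA_real_
  out$degenerate <- FALSE

  tt <- trace$times_s
  vv <- trace$o2_fraction
  for (i in seq_len(nrow(b))) {
    onset <- b$start_s[i]
    pre <- which(tt < onset)
    ci <- if (length(pre)) vv[max(pre)] else vv[min(which(tt >= onset))]
    cf <- plateaus$plateau_fraction[i]
    if (!is.finite(ci) || !is.finite(cf)) next
    if (isTRUE(all.equal(ci, cf))) {
      out[i, tcol] <- 0
      out$degenerate[i] <- TRUE
      next
    }
    dir <- sign(cf - ci)
    sel <- which(tt >= onset & tt < b$end_s[i])
    if (i == nrow(b)) sel <- which(tt >= onset & tt <= b$end_s[i])
    if (!length(sel)) next
    ts <- tt[sel]; vs <- vv[sel]
    for (j in seq_along(thresholds)) {
      thr <- ci + thresholds[j] * (cf - ci)
      rel <- (vs - thr) * dir
      hit <- rel >= 0
      if (sustained) {
        # first index from which the trace never falls back past thr
        stay <- rev(cumprod(rev(as.numeric(hit)))) > 0
        k <- if (any(stay)) min(which(stay)) else NA_integer_
      } else {
        k <- if (any(hit)) min(which(hit)) else NA_integer_
      }
      if (is.na(k)) next
      if (k == 1L) {
        out[i, tcol[j]] <- (ts[1] - onset) / 60
      } else {
        # linear interpolation between samples k-1 and k
        f <- (thr - vs[k - 1]) / (vs[k] - vs[k - 1])
        out[i, tcol[j]] <- (ts[k - 1] + f * (ts[k] - ts[k - 1]) - onset) / 60
      }
    }
  }
  class(out) <- c("switching_times", "data.frame")
  out
}
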