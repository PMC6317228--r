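#' Playback configuration for the software simulator surrogate
#'
#' One cam revolution produces one pulse; the follower lift is mapped
#' linearly to pressure between the commanded diastolic level and diastolic
#' plus pulse pressure. An optional first-order lag emulates the softening of
#' the systolic upstroke caused by the compressibility of the working air;
#' it is a deliberately minimal surrogate for the pneumatics (which this
#' package does not model) and is off by default.
#'
#' @param heart_rate_bpm Cam speed in revolutions per minute (> 0).
#' @param pulse_pressure_mmHg Commanded output max minus min (> 0).
#' @param diastolic_mmHg Commanded output minimum.
#' @param lag_tau_s First-order time constant in seconds (0 disables).
#' @param sample_rate_hz Output sampling rate.
#' @param duration_s Record duration in seconds.
#' @param noise_sd_mmHg Optional additive Gaussian measurement noise
#'   (default 0; the caller controls the RNG seed).
#' @return An object of class `playback_config`.
#' @export
playback_config <- function(heart_rate_bpm = 60, pulse_pressure_mmHg = 50,
                            diastolic_mmHg = 80, lag_tau_s = 0,
                            sample_rate_hz = 1000, duration_s = 10,
                            noise_sd_mmHg = 0) {
  if (!(heart_rate_bpm > 0)) stop("heart_rate_bpm must be > 0", call. = FALSE)
  if (!(pulse_pressure_mmHg > 0)) stop("pulse_pressure_mmHg must be > 0", call. = FALSE)
  if (lag_tau_s < 0) stop("lag_tau_s must be >= 0", call. = FALSE)
  if (!(sample_rate_hz > 0) || !(duration_s > 0)) {
    stop("sample_rate_hz and duration_s must be > 0", call. = FALSE)
  }
  structure(
    list(heart_rate_bpm = heart_rate_bpm,
         pulse_pressure_mmHg = pulse_pressure_mmHg,
         diastolic_mmHg = diastolic_mmHg, lag_tau_s = lag_tau_s,
         sample_rate_hz = sample_rate_hz, duration_s = duration_s,
         noise_sd_mmHg = noise_sd_mmHg),
    class = "playback_config"
  )
}

#' Simulate the pressure waveform produced by rotating a cam
#'
#' The cam angle advances kinematically,
#' `theta(t) = 360 * (heart_rate_bpm / 60) * t mod 360`, so the realized
#' period is exactly `60 / heart_rate_bpm` seconds. The ideal pressure is
#' `p0(t) = diastolic + pulse_pressure * lift(theta(t)) / stroke`. With
#' `lag_tau_s > 0` the output solves `y' = (p0 - y) / tau`, integrated
#' exactly for piecewise-linear input (exponential integrator) from
#' `y(0) = p0(0)`.
#'
#' @param profile A [cam_profile()].
#' @param config A [playback_config()].
#' @return A [sampled_waveform()] in mmHg on a time abscissa, with the pulse
#'   period recorded in attribute `"pulse_period_s"`.
#' @examples
#' cam <- waveform_to_cam(reference_radial_series(), 20, 5, n_points = 720)
#' w <- simulate_pressure(cam, playback_config(duration_s = 3))
#' range(w$values)
#' @export
simulate_pressure <- function(profile, config) {
  stopifnot(inherits(profile, "cam_profile"),
            inherits(config, "playback_config"))
  period <- 60 / config$heart_rate_bpm
  if (config$sample_rate_hz * period < 50) {
    stop("sample_rate_hz too low: need at least 50 samples per pulse period",
         call. = FALSE)
  }
  n <- as.integer(round(config$duration_s * config$sample_rate_hz))
  t <- (seq_len(n) - 1) / config$sample_rate_hz
  theta <- (360 * t / period) %% 360
  lift <- cam_to_displacement(profile, theta)
  p0 <- config$diastolic_mmHg +
    config$pulse_pressure_mmHg * lift / profile$stroke_mm

  y <- p0
  if (config$lag_tau_s > 0) {
    y <- first_order_lag(p0, 1 / config$sample_rate_hz, config$lag_tau_s)
  }
  if (config$noise_sd_mmHg > 0) {
    y <- y + stats::rnorm(n, sd = config$noise_sd_mmHg)
  }
  out <- sampled_waveform(y, abscissa = t, period = period, units = "mmHg")
  attr(out, "pulse_period_s") <- period
  out
}

# Exact discrete solution of y' = (x - y)/tau for input x linear between
# samples: y_{k+1} = y_k e^{-a} + x_k (1 - e^{-a})
#                  + (x_{k+1} - x_k) (1 - (1 - e^{-a}) / a),  a = dt/tau.
#' @keywords internal
#' @noRd
first_order_lag <- function(x, dt, tau) {
  a <- dt / tau
  ea <- exp(-a)
  c0 <- 1 - ea
  c1 <- 1 - c0 / a
  n <- length(x)
  y <- numeric(n)
  y[1] <- x[1]
  for (k in seq_len(n - 1)) {
    y[k + 1] <- y[k] * ea + x[k] * c0 + (x[k + 1] - x[k]) * c1
  }
  y
}

#' Extract a steady-state pulse ensemble from a simulated record
#'
#' Discards the initial transient (first `transient_periods` pulse periods),
#' segments the remainder foot-to-foot, and normalizes the first `n_pulses`
#' pulses onto a common grid.
#'
#' @param record A [sampled_waveform()] on a time abscissa; at least
#'   `n_pulses + transient_periods` periods long.
#' @param n_pulses Number of pulses to keep.
#' @param period_s Pulse period hint; defaults to the record's
#'   `"pulse_period_s"` attribute when present, otherwise estimated from
#'   segmentation.
#' @param grid_n Common grid size for the normalized pulses (default 200).
#' @param transient_periods Periods discarded from the head (default 2).
#' @param ... Passed to [segment_pulses()].
#' @return A [pulse_ensemble()].
#' @export
steady_state_extract <- function(record, n_pulses, period_s = NULL,
                                 grid_n = 200, transient_periods = 2, ...) {
  stopifnot(inherits(record, "sampled_waveform"))
  if (is.null(period_s)) period_s <- attr(record, "pulse_period_s")
  dt <- waveform_dt(record)
  dur <- length(record$values) * dt
  if (!is.null(period_s) && dur < (n_pulses + transient_periods) * period_s) {
    stop(sprintf(
      "record too short: %.3g s < %d pulses + %d transient periods at %.3g s",
      dur, n_pulses, transient_periods, period_s), call. = FALSE)
  }
  skip <- if (is.null(period_s)) 0L else
    as.integer(round(transient_periods * period_s / dt))
  idx <- (skip + 1):length(record$values)
  trimmed <- sampled_waveform(record$values[idx],
                              abscissa = record$abscissa[idx],
                              units = record$units)
  pulses <- segment_pulses(trimmed, ...)
  if (length(pulses) < n_pulses) {
    stop(sprintf("record too short: only %d full pulses after the transient, need %d",
                 length(pulses), n_pulses), call. = FALSE)
  }
  pulses <- pulses[seq_len(n_pulses)]
  norm <- lapply(pulses, function(p) resample_pulse(normalize_pulse(p), grid_n))
  # resampling can nudge the extrema off exactly {0, 1}; re-scale on the grid
  norm <- lapply(norm, normalize_pulse)
  pulse_ensemble(norm, source_label = "steady_state_extract")
}
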