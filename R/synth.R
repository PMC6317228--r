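#' Specification of a synthetic steady-state pulse ensemble
#'
#' Describes the generator that emulates a steady-state tonometry ensemble:
#' around 40 consecutive three-peak radial pulses (percussion peak,
#' late-systolic shoulder, dicrotic wave) with per-pulse amplitude and
#' late-peak-height jitter, period jitter for continuous records, and
#' additive measurement noise. Every drawn perturbation is logged so each
#' pulse's true augmentation index is known ground truth.
#'
#' @param n_pulses Ensemble size (default 40).
#' @param kind Base pulse shape: `"table"` uses the packaged representative
#'   Fourier coefficients ([reference_radial_series()]); `"gaussians"` builds
#'   a three-Gaussian pulse from `base_params`.
#' @param base_params For `kind = "gaussians"`: list with `phases`, `heights`,
#'   `widths` of the three bumps. Defaults place the percussion peak at
#'   phase 0.15 (height 1), the late-systolic shoulder at 0.35 (height
#'   0.695, mimicking a typical young-adult male AI of about 69.5%), and the
#'   dicrotic wave at 0.60 (height 0.30), all with width 0.05.
#' @param amplitude_jitter_pct Per-pulse amplitude scale s.d., percent
#'   (default 2).
#' @param period_jitter_pct Per-pulse period s.d., percent (default 2; used
#'   by [generate_continuous_record()]).
#' @param ai_jitter_pct Per-pulse late-peak height scale s.d., percent
#'   (default 3).
#' @param noise_sd Additive Gaussian noise s.d. in normalized units
#'   (default 0.01).
#' @param seed Integer RNG seed; the generator is fully seed-deterministic.
#' @param grid_n Common pulse grid size (default 200).
#' @param base_period_s Nominal pulse period for continuous records
#'   (default 0.9 s, a resting heart rate of about 67 bpm).
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_pulses = 40, kind = c("table", "gaussians"),
                          base_params = NULL, amplitude_jitter_pct = 2,
                          period_jitter_pct = 2, ai_jitter_pct = 3,
                          noise_sd = 0.01, seed = 1, grid_n = 200,
                          base_period_s = 0.9) {
  kind <- match.arg(kind)
  if (n_pulses < 2) stop("n_pulses must be >= 2", call. = FALSE)
  if (any(c(amplitude_jitter_pct, period_jitter_pct, ai_jitter_pct,
            noise_sd) < 0)) {
    stop("jitters and noise_sd must be >= 0", call. = FALSE)
  }
  structure(
    list(n_pulses = as.integer(n_pulses), kind = kind,
         base_params = base_params,
         amplitude_jitter_pct = amplitude_jitter_pct,
         period_jitter_pct = period_jitter_pct,
         ai_jitter_pct = ai_jitter_pct, noise_sd = noise_sd,
         seed = as.integer(seed), grid_n = as.integer(grid_n),
         base_period_s = base_period_s),
    class = "ensemble_spec"
  )
}

#' Build a noise-free base pulse
#'
#' @param kind `"table"` evaluates the packaged representative Fourier
#'   coefficients on the pulse grid (keeping their published normalized
#'   scale); `"gaussians"` sums three Gaussian bumps and min-max normalizes.
#' @param params For `"gaussians"`: list(`phases`, `heights`, `widths`);
#'   `widths` is recycled. All peak phases must lie in `[0, 1)`.
#' @param n Grid size (default 200).
#' @return A [sampled_waveform()] on a normalized scale.
#' @examples
#' p <- make_base_pulse("gaussians")
#' radial_ai(p)$ai_percent
#' @export
make_base_pulse <- function(kind = c("table", "gaussians"), params = NULL,
                            n = 200) {
  kind <- match.arg(kind)
  if (kind == "table") {
    return(fourier_waveform(reference_radial_series(), n = n, units = "au"))
  }
  p <- default_gaussian_params(params)
  if (any(p$phases < 0 | p$phases >= 1)) {
    stop("Gaussian peak phases must lie in [0, 1)", call. = FALSE)
  }
  ph <- (seq_len(n) - 1) / n
  v <- gaussian_mixture(ph, p)
  rng <- range(v)
  sampled_waveform((v - rng[1]) / (rng[2] - rng[1]), abscissa = ph,
                   period = 1, units = "normalized")
}

#' @keywords internal
#' @noRd
default_gaussian_params <- function(params) {
  p <- list(phases = c(0.15, 0.35, 0.60), heights = c(1, 0.695, 0.30),
            widths = 0.05)
  if (!is.null(params)) p[names(params)] <- params
  p$widths <- rep_len(p$widths, length(p$phases))
  p
}

#' @keywords internal
#' @noRd
gaussian_mixture <- function(ph, p) {
  v <- numeric(length(ph))
  for (j in seq_along(p$phases)) {
    v <- v + p$heights[j] * exp(-(ph - p$phases[j])^2 / (2 * p$widths[j]^2))
  }
  v
}

# Narrow bump centred on the base pulse's late-systolic peak; adding
# (s - 1) * late_height * bump scales the late peak height by exactly s
# while leaving the other peaks essentially untouched.
#' @keywords internal
#' @noRd
late_peak_bump <- function(spec, base) {
  det <- detect_systolic_peaks(base, smooth = "none")
  width <- if (spec$kind == "gaussians") {
    default_gaussian_params(spec$base_params)$widths[2]
  } else {
    0.03
  }
  ph <- waveform_phases(base)
  list(shape = exp(-(ph - det$late$phase)^2 / (2 * width^2)),
       height = det$late$value)
}

#' Generate a synthetic steady-state pulse ensemble with ground truth
#'
#' Each pulse is a perturbed copy of the base pulse: an amplitude scale
#' `~ Normal(1, amplitude_jitter)`, a late-peak height scale
#' `~ Normal(1, ai_jitter)` applied through a narrow bump at the late-peak
#' phase, additive `Normal(0, noise_sd)` noise, then min-max renormalization.
#' The log records each pulse's drawn scales and its true (noise-free) AI;
#' the ensemble mean of those true AIs is the generator's ground truth.
#'
#' @param spec An [ensemble_spec()].
#' @return A list with `ensemble` (a [pulse_ensemble()]) and `log` (a data
#'   frame with columns `pulse`, `amp_scale`, `ai_scale`, `ai_true`, plus
#'   attribute `mean_ai_true`).
#' @examples
#' out <- generate_ensemble(ensemble_spec(n_pulses = 5, seed = 42))
#' attr(out$log, "mean_ai_true")
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  base <- make_base_pulse(spec$kind, spec$base_params, n = spec$grid_n)
  bump <- late_peak_bump(spec, base)
  ph <- waveform_phases(base)
  m <- spec$n_pulses

  amp_scale <- stats::rnorm(m, 1, spec$amplitude_jitter_pct / 100)
  ai_scale <- stats::rnorm(m, 1, spec$ai_jitter_pct / 100)
  pulses <- vector("list", m)
  ai_true <- numeric(m)
  for (i in seq_len(m)) {
    shaped <- base$values + (ai_scale[i] - 1) * bump$height * bump$shape
    clean <- renormalize_values(amp_scale[i] * shaped)
    ai_true[i] <- radial_ai(clean)$ai_percent
    noisy <- amp_scale[i] * shaped +
      stats::rnorm(spec$grid_n, sd = spec$noise_sd)
    pulses[[i]] <- sampled_waveform(renormalize_values(noisy)$values,
                                    abscissa = ph, period = 1,
                                    units = "normalized")
  }
  log <- data.frame(pulse = seq_len(m), amp_scale = amp_scale,
                    ai_scale = ai_scale, ai_true = ai_true)
  attr(log, "mean_ai_true") <- mean(ai_true)
  list(ensemble = pulse_ensemble(pulses,
                                 source_label = sprintf("synthetic %s seed %d",
                                                        spec$kind, spec$seed)),
       log = log)
}

#' @keywords internal
#' @noRd
renormalize_values <- function(v) {
  rng <- range(v)
  sampled_waveform((v - rng[1]) / (rng[2] - rng[1]), period = 1,
                   units = "normalized")
}

#' Generate a continuous multi-pulse record for segmentation testing
#'
#' Concatenates the ensemble's perturbed pulses in time, each resampled to
#' its own drawn period (`~ Normal(base_period_s, period_jitter)`) and
#' anchored at its diastolic foot so that pulse boundaries are genuine feet.
#' Optionally prepends a linear amplitude ramp emulating the pressurization
#' phase of a tonometry recording. Noise is added to the whole record.
#'
#' @param spec An [ensemble_spec()].
#' @param include_ramp Prepend a pressurization ramp (default `FALSE`).
#' @param sample_rate_hz Record sampling rate (default 250).
#' @param ramp_s Ramp duration in seconds (default 3).
#' @return A list with `record` (a [sampled_waveform()], units `"au"`) and
#'   `log` (data frame with drawn and realized per-pulse periods, plus
#'   attributes `feet_s`, `ramp_samples`).
#' @export
generate_continuous_record <- function(spec, include_ramp = FALSE,
                                       sample_rate_hz = 250, ramp_s = 3) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  base <- make_base_pulse(spec$kind, spec$base_params, n = spec$grid_n)
  bump <- late_peak_bump(spec, base)
  m <- spec$n_pulses
  dt <- 1 / sample_rate_hz

  amp_scale <- stats::rnorm(m, 1, spec$amplitude_jitter_pct / 100)
  ai_scale <- stats::rnorm(m, 1, spec$ai_jitter_pct / 100)
  periods <- spec$base_period_s *
    stats::rnorm(m, 1, spec$period_jitter_pct / 100)

  # anchor every pulse at the base pulse's diastolic foot
  foot <- which.min(base$values)
  roll <- function(v) v[c(foot:length(v), seq_len(foot - 1))]

  segments <- vector("list", m)
  n_samp <- integer(m)
  for (i in seq_len(m)) {
    shaped <- amp_scale[i] *
      (base$values + (ai_scale[i] - 1) * bump$height * bump$shape)
    pulse <- sampled_waveform(roll(shaped), period = 1, units = "au")
    n_samp[i] <- max(16L, as.integer(round(periods[i] / dt)))
    segments[[i]] <- resample_pulse(pulse, n_samp[i])$values
  }
  values <- unlist(segments)

  ramp_samples <- 0L
  if (include_ramp) {
    ramp_samples <- as.integer(round(ramp_s / dt))
    tile <- resample_pulse(sampled_waveform(roll(base$values), period = 1,
                                            units = "au"),
                           max(16L, as.integer(round(spec$base_period_s / dt))))$values
    ramp <- rep_len(tile, ramp_samples) *
      seq(0, 1, length.out = ramp_samples)
    values <- c(ramp, values)
  }
  if (spec$noise_sd > 0) {
    values <- values + stats::rnorm(length(values), sd = spec$noise_sd)
  }

  record <- sampled_waveform(values,
                             abscissa = (seq_along(values) - 1) * dt,
                             units = "au")
  log <- data.frame(pulse = seq_len(m), period_drawn_s = periods,
                    period_realized_s = n_samp * dt,
                    amp_scale = amp_scale, ai_scale = ai_scale)
  attr(log, "feet_s") <- (ramp_samples + cumsum(c(0L, n_samp[-m]))) * dt
  attr(log, "ramp_samples") <- ramp_samples
  list(record = record, log = log)
}
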