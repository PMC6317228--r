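#' Discrete Fourier transform of one pulse period
#'
#' Computes `S(f) = sum_{m=1..N} y(m/N) exp(-2 pi i f m / N)` for harmonic
#' indices `f = 0..N-1`, the 1-based summation over samples at phases
#' `1/N, 2/N, ..., 1`. Because the pulse is periodic (`y(1) = y(0)`), this
#' equals the standard 0-based FFT of the samples at phases
#' `0, 1/N, ..., (N-1)/N`, which is how it is computed.
#'
#' @param waveform A [sampled_waveform()]; resampled to `n` points first when
#'   needed.
#' @param n DFT length (default 200).
#' @return Complex vector of length `n`; element `f + 1` is harmonic `f`.
#' @export
pulse_dft <- function(waveform, n = 200) {
  stopifnot(inherits(waveform, "sampled_waveform"))
  if (length(waveform$values) != n) {
    waveform <- resample_pulse(waveform, n)
  }
  stats::fft(waveform$values)
}

#' Phase angle of a spectrum bin, in degrees
#'
#' Two-argument arctangent of the bin's imaginary and real parts, wrapped to
#' `(-180, 180]`. Refuses bins whose magnitude is negligible relative to the
#' total spectrum, where the phase is numerically undefined.
#'
#' @param spectrum Complex spectrum as returned by [pulse_dft()].
#' @param harmonic Harmonic index (1 = fundamental).
#' @return Phase angle in degrees.
#' @export
phase_angle_deg <- function(spectrum, harmonic) {
  harmonic <- as.integer(harmonic)
  if (harmonic < 0 || harmonic >= length(spectrum)) {
    stop("harmonic index out of range", call. = FALSE)
  }
  bin <- spectrum[harmonic + 1]
  if (Mod(bin) <= 1e-12 * sum(Mod(spectrum))) {
    stop(sprintf("phase undefined: negligible magnitude at harmonic %d", harmonic),
         call. = FALSE)
  }
  wrap_deg(atan2(Im(bin), Re(bin)) * 180 / pi)
}

#' Phase-angle delay between a reference and a simulated waveform
#'
#' Both waveforms are normalized and resampled to a common DFT length; the
#' delay at each requested harmonic is the reference phase minus the
#' simulated phase, wrapped to `(-180, 180]`. A positive delay means the
#' simulated waveform lags the reference. The fundamental-harmonic delay is
#' also expressed as a percentage of one 360-degree cycle.
#'
#' Harmonics are counted on the normalized single-pulse period; for a 60 bpm
#' pulse, harmonics 1 and 2 coincide with 1 Hz and 2 Hz.
#'
#' @param reference,simulated [sampled_waveform()]s (or normalized pulses).
#' @param harmonics Integer vector of harmonics to compare (default `c(1, 2)`).
#' @param n DFT length (default 200).
#' @param n_amplitudes Number of harmonic amplitudes reported (default 20).
#' @return An object of class `phase_delay_report`: list with `n_samples`,
#'   `harmonics`, `amplitudes_ref`, `amplitudes_sim` (magnitudes at harmonics
#'   `1..n_amplitudes`), `phase_ref_deg`, `phase_sim_deg`, `delay_deg` (per
#'   requested harmonic) and `delay_percent_of_cycle` (harmonic 1).
#' @examples
#' w <- fourier_waveform(reference_radial_series(), 200)
#' rep <- phase_delay(w, w)
#' rep$delay_deg
#' @export
phase_delay <- function(reference, simulated, harmonics = c(1, 2), n = 200,
                        n_amplitudes = 20) {
  prep <- function(w) {
    stopifnot(inherits(w, "sampled_waveform"))
    if (!w$units %in% c("normalized", "au")) w <- normalize_pulse(w)
    pulse_dft(w, n)
  }
  sp_ref <- prep(reference)
  sp_sim <- prep(simulated)
  ks <- seq_len(min(n_amplitudes, n %/% 2))
  phase_ref <- vapply(harmonics, function(h) phase_angle_deg(sp_ref, h), numeric(1))
  phase_sim <- vapply(harmonics, function(h) phase_angle_deg(sp_sim, h), numeric(1))
  delay <- wrap_deg(phase_ref - phase_sim)
  names(phase_ref) <- names(phase_sim) <- names(delay) <-
    paste0("h", harmonics)
  pct <- if (1 %in% harmonics) delay[[which(harmonics == 1)[1]]] / 360 * 100 else NA_real_
  structure(
    list(n_samples = n, harmonics = harmonics,
         amplitudes_ref = Mod(sp_ref[ks + 1]),
         amplitudes_sim = Mod(sp_sim[ks + 1]),
         phase_ref_deg = phase_ref, phase_sim_deg = phase_sim,
         delay_deg = delay, delay_percent_of_cycle = pct),
    class = "phase_delay_report"
  )
}

#' @export
print.phase_delay_report <- function(x, ...) {
  cat(sprintf("<phase_delay_report> N = %d\n", x$n_samples))
  for (i in seq_along(x$harmonics)) {
    cat(sprintf("  harmonic %d: ref %8.3f deg, sim %8.3f deg, delay %8.3f deg\n",
                x$harmonics[i], x$phase_ref_deg[i], x$phase_sim_deg[i],
                x$delay_deg[i]))
  }
  if (is.finite(x$delay_percent_of_cycle)) {
    cat(sprintf("  delay at harmonic 1 = %.2f%% of one cycle\n",
                x$delay_percent_of_cycle))
  }
  invisible(x)
}

#' Convert a phase-angle delay to percent of one cycle
#'
#' @param delay_deg Delay in degrees.
#' @return `delay_deg / 360 * 100`.
#' @examples
#' delay_as_percent_of_cycle(11.4) # 3.2 (1 d.p.)
#' @export
delay_as_percent_of_cycle <- function(delay_deg) delay_deg / 360 * 100
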