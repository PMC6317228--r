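# A sinusoidal cam makes the first-order lag analytically checkable.
sine_cam <- function(n = 3600) {
  u <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  cam_profile((0:(n - 1)) * 360 / n, 20 + 5 * u, 20, 5)
}

# one full period cut at a period boundary, as a standalone waveform
cut_period <- function(w, start_s, rate) {
  i0 <- as.integer(round(start_s * rate)) + 1L
  n <- as.integer(round(attr(w, "pulse_period_s") * rate))
  idx <- i0:(i0 + n - 1)
  sampled_waveform(w$values[idx], abscissa = w$abscissa[idx],
                   period = attr(w, "pulse_period_s"), units = "mmHg")
}

test_that("tau = 0 playback realizes the commanded pressures and period exactly", {
  cam <- waveform_to_cam(reference_radial_series(), 20, 5, n_points = 720)
  cfg <- playback_config(heart_rate_bpm = 60, pulse_pressure_mmHg = 50,
                         diastolic_mmHg = 80, sample_rate_hz = 720,
                         duration_s = 4)
  w <- simulate_pressure(cam, cfg)
  expect_equal(min(w$values), 80)
  expect_equal(max(w$values), 130)
  expect_equal(attr(w, "pulse_period_s"), 1)
  # consecutive periods are bit-identical (rotation is kinematic)
  expect_equal(w$values[1:720], w$values[721:1440], tolerance = 1e-12)

  # the played-back pulse equals the cam waveform after normalization
  one <- cut_period(w, 1, 720)
  u <- (cam$radii_mm - 20) / 5
  expect_lt(max(abs(normalize_pulse(one)$values - u)), 1e-6)
})

test_that("first-order lag reproduces the analytic phase and attenuation", {
  cam <- sine_cam()
  rate <- 1800
  mk <- function(tau) {
    simulate_pressure(cam, playback_config(
      heart_rate_bpm = 60, pulse_pressure_mmHg = 50, diastolic_mmHg = 80,
      lag_tau_s = tau, sample_rate_hz = rate, duration_s = 8))
  }
  w0 <- mk(0)
  w1 <- mk(0.02)
  rep <- phase_delay(cut_period(w0, 5, rate), cut_period(w1, 5, rate),
                     harmonics = 1)
  analytic <- atan(2 * pi * 1 * 0.02) * 180 / pi # 7.2 degrees
  expect_lt(abs(rep$delay_deg[[1]] - analytic), 0.3)

  # amplitude attenuation of the steady-state sinusoid: |H| = 1/sqrt(1+(2 pi f tau)^2)
  seg <- w1$values[(5 * rate):(8 * rate)]
  att <- (max(seg) - min(seg)) / 50
  expect_equal(att, 1 / sqrt(1 + (2 * pi * 0.02)^2), tolerance = 1e-3)
})

test_that("phase delay grows monotonically with the lag time constant", {
  cam <- waveform_to_cam(reference_radial_series(), 20, 5, n_points = 720)
  rate <- 1200
  ref <- simulate_pressure(cam, playback_config(
    heart_rate_bpm = 60, sample_rate_hz = rate, duration_s = 6))
  delays <- vapply(c(0.005, 0.01, 0.02, 0.04), function(tau) {
    w <- simulate_pressure(cam, playback_config(
      heart_rate_bpm = 60, lag_tau_s = tau, sample_rate_hz = rate,
      duration_s = 6))
    phase_delay(cut_period(ref, 4, rate), cut_period(w, 4, rate))$delay_deg[[1]]
  }, numeric(1))
  expect_true(all(delays > 0))
  expect_true(all(diff(delays) > 0))
})

test_that("steady_state_extract returns identical settled pulses", {
  cam <- waveform_to_cam(reference_radial_series(), 20, 5, n_points = 3600)
  w <- simulate_pressure(cam, playback_config(
    heart_rate_bpm = 75, sample_rate_hz = 900, duration_s = 10))
  ens <- steady_state_extract(w, 8)
  expect_s3_class(ens, "pulse_ensemble")
  expect_identical(length(ens$pulses), 8L)
  for (i in 2:8) {
    expect_lt(max(abs(ens$pulses[[i]]$values - ens$pulses[[1]]$values)), 1e-9)
  }

  # with lag: later pulses are mutually identical once settled
  wl <- simulate_pressure(cam, playback_config(
    heart_rate_bpm = 75, lag_tau_s = 0.03, sample_rate_hz = 900,
    duration_s = 10))
  ensl <- steady_state_extract(wl, 8)
  for (i in 4:8) {
    expect_lt(max(abs(ensl$pulses[[i]]$values - ensl$pulses[[3]]$values)), 1e-6)
  }
})

test_that("playback parameter validation", {
  cam <- sine_cam(360)
  expect_error(simulate_pressure(cam, playback_config(
    heart_rate_bpm = 75, sample_rate_hz = 40, duration_s = 5)),
    "50 samples")
  w <- simulate_pressure(cam, playback_config(duration_s = 3))
  expect_error(steady_state_extract(w, 10), "too short")
  expect_error(playback_config(heart_rate_bpm = -5), "heart_rate_bpm")
  expect_error(playback_config(lag_tau_s = -1), "lag_tau_s")
})
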