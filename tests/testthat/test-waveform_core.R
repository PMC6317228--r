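test_that("read_waveform parses delimited text and validates the abscissa", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,10", "0.01,12", "0.02,11"), f)
  w <- read_waveform(f)
  expect_s3_class(w, "sampled_waveform")
  expect_length(w$values, 3)
  expect_equal(w$abscissa[2] - w$abscissa[1], 0.01)
  expect_equal(w$values, c(10, 12, 11))

  writeLines(c("time_s\tpressure", "0\t10", "0.01\t12", "0.02\t11"), f)
  expect_equal(read_waveform(f)$values, c(10, 12, 11))

  writeLines(c("0.02,11", "0,10", "0.01,12"), f)
  expect_error(read_waveform(f), "non-monotone abscissa")

  writeLines(c("0,10", "0.01,oops", "0.02,11"), f)
  expect_error(read_waveform(f), "line 2")

  writeLines(c("0,10", "0.01,12", "0.5,11"), f)
  expect_error(read_waveform(f), "non-uniform")
})

test_that("write/read round-trip is lossless to 1e-12", {
  set.seed(5)
  w <- sampled_waveform(80 + 40 * runif(64), abscissa = (0:63) / 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveform(w, f)
  w2 <- read_waveform(f)
  expect_waveform_equal(w, w2, tol = 1e-12)
})

test_that("normalize_pulse min-max scales, is idempotent and affine-invariant", {
  v <- 60 + 50 * (0.5 - 0.5 * cos(2 * pi * (0:79) / 80))
  p <- sampled_waveform(v, abscissa = (0:79) / 100, period = 0.8)
  np <- normalize_pulse(p)
  expect_equal(min(np$values), 0)
  expect_equal(max(np$values), 1)
  expect_equal(np$period, 1)
  expect_identical(np$units, "normalized")

  expect_equal(normalize_pulse(np)$values, np$values, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:10) {
    a <- runif(1, 0.1, 10)
    b <- runif(1, -50, 50)
    q <- sampled_waveform(a * v + b, abscissa = p$abscissa, period = 0.8)
    expect_equal(normalize_pulse(q)$values, np$values, tolerance = 1e-9)
  }

  expect_error(normalize_pulse(sampled_waveform(rep(5, 20))), "constant")
})

test_that("resample_pulse interpolates periodically at the stated accuracy", {
  ph <- (0:49) / 50
  p <- sampled_waveform(sin(2 * pi * ph), abscissa = ph, period = 1, units = "au")

  same <- resample_pulse(p, 50)
  expect_equal(same$values, p$values, tolerance = 1e-9)

  fine_spline <- resample_pulse(p, 200, method = "spline")
  expect_lt(max(abs(fine_spline$values - sin(2 * pi * (0:199) / 200))), 1e-3)

  # linear interpolation is bounded by h^2 max|f''| / 8
  fine_lin <- resample_pulse(p, 200)
  expect_lt(max(abs(fine_lin$values - sin(2 * pi * (0:199) / 200))), 2.5e-3)

  # refinement consistency
  q <- two_gauss_pulse(n = 100)
  r1 <- resample_pulse(resample_pulse(q, 400), 200)
  r2 <- resample_pulse(q, 200)
  expect_equal(r1$values, r2$values, tolerance = 1e-6)

  expect_error(resample_pulse(p, 8), ">= 16")
})

test_that("ensemble_mean equals the brute-force per-point average", {
  out <- generate_ensemble(ensemble_spec(n_pulses = 40, seed = 9))
  ens <- out$ensemble
  mn <- ensemble_mean(ens)
  brute <- numeric(ens$grid_n)
  for (j in seq_len(ens$grid_n)) {
    acc <- 0
    for (p in ens$pulses) acc <- acc + p$values[j]
    brute[j] <- acc / length(ens$pulses)
  }
  expect_equal(mn$values, brute, tolerance = 1e-12)

  # mean of identical pulses is that pulse; mean of p and 1-p is flat 0.5
  p <- two_gauss_pulse()
  same <- pulse_ensemble(list(p, p, p))
  expect_equal(ensemble_mean(same)$values, p$values, tolerance = 1e-12)
  q <- sampled_waveform(1 - p$values, abscissa = p$abscissa, period = 1,
                        units = "normalized")
  expect_equal(ensemble_mean(pulse_ensemble(list(p, q)))$values,
               rep(0.5, 200), tolerance = 1e-12)
})

test_that("segmentation recovers tiled and period-jittered pulses", {
  # exact tiling of one pulse: every recovered period matches the tile length
  spec0 <- ensemble_spec(n_pulses = 5, amplitude_jitter_pct = 0,
                         period_jitter_pct = 0, ai_jitter_pct = 0,
                         noise_sd = 0, seed = 1)
  rec0 <- generate_continuous_record(spec0)
  pulses0 <- segment_pulses(rec0$record)
  expect_true(length(pulses0) %in% c(4, 5))
  expect_equal(as.numeric(attr(pulses0, "periods_s")),
               rec0$log$period_realized_s[seq_along(pulses0)],
               tolerance = 1 / 250 + 1e-12)

  # 5% period jitter: per-pulse periods match the generator log within 1 sample
  spec <- ensemble_spec(n_pulses = 10, period_jitter_pct = 5, noise_sd = 0,
                        seed = 3)
  rec <- generate_continuous_record(spec)
  pulses <- segment_pulses(rec$record)
  expect_gte(length(pulses), 8)
  expect_lt(max(abs(attr(pulses, "periods_s") -
                      rec$log$period_realized_s[seq_along(pulses)])),
            1 / 250 + 1e-12)

  expect_error(segment_pulses(sampled_waveform(rep(3, 500), abscissa = (0:499) / 100)),
               "segmentation error")
})

test_that("segmentation of the post-ramp region recovers correct periods", {
  spec <- ensemble_spec(n_pulses = 8, noise_sd = 0, seed = 5)
  out <- generate_continuous_record(spec, include_ramp = TRUE, ramp_s = 3)
  r <- out$record
  keep <- r$abscissa >= 3
  post <- sampled_waveform(r$values[keep], abscissa = r$abscissa[keep],
                           units = "au")
  pulses <- segment_pulses(post)
  expect_gte(length(pulses), 6)
  expect_lt(max(abs(attr(pulses, "periods_s") -
                      out$log$period_realized_s[seq_along(pulses)])),
            1 / 250 + 1e-12)
})

test_that("segment + normalize + mean is invariant to affine rescaling", {
  spec <- ensemble_spec(n_pulses = 6, period_jitter_pct = 3, noise_sd = 0,
                        seed = 13)
  rec <- generate_continuous_record(spec)$record
  pipeline <- function(record) {
    pulses <- segment_pulses(record)
    norm <- lapply(pulses, function(p) resample_pulse(normalize_pulse(p), 200))
    ensemble_mean(pulse_ensemble(lapply(norm, normalize_pulse)))
  }
  m1 <- pipeline(rec)
  rec2 <- sampled_waveform(3.7 * rec$values + 25, abscissa = rec$abscissa,
                           units = "au")
  m2 <- pipeline(rec2)
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
})

test_that("tiling one pulse yields segments matching the normalized source", {
  spec <- ensemble_spec(n_pulses = 5, amplitude_jitter_pct = 0,
                        period_jitter_pct = 0, ai_jitter_pct = 0,
                        noise_sd = 0, seed = 1)
  rec <- generate_continuous_record(spec)
  pulses <- segment_pulses(rec$record)
  base <- make_base_pulse("table", n = 200)
  foot <- which.min(base$values)
  rolled <- base$values[c(foot:200, seq_len(foot - 1))]
  ref <- normalize_pulse(sampled_waveform(rolled, period = 1, units = "au"))
  for (p in pulses) {
    got <- resample_pulse(normalize_pulse(p), 200)
    # one-sample phase tolerance on the source grid
    shift_err <- min(vapply(c(-1, 0, 1), function(s) {
      max(abs(got$values - ref$values[((seq_len(200) - 1 + s) %% 200) + 1]))
    }, numeric(1)))
    expect_lt(shift_err, 0.05)
  }
})
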