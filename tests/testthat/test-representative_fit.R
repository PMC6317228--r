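test_that("evaluate_series honours the trigonometric basis and periodicity", {
  const <- fourier_series(1, numeric(3), numeric(3))
  expect_equal(evaluate_series(const, c(0, 0.3, 0.77)), rep(1, 3))

  cos1 <- fourier_series(0, c(1, 0), c(0, 0))
  expect_equal(evaluate_series(cos1, 0), 1)
  expect_equal(evaluate_series(cos1, 0.25), 0, tolerance = 1e-12)

  s <- reference_radial_series()
  expect_equal(evaluate_series(s, 0), evaluate_series(s, 1), tolerance = 1e-12)
  expect_equal(evaluate_series(s, -0.25), evaluate_series(s, 0.75),
               tolerance = 1e-12)
})

test_that("packaged series has exactly three local maxima per period", {
  v <- evaluate_series(reference_radial_series(), (0:1999) / 2000)
  n <- length(v)
  n_max <- sum(v > v[c(n, 1:(n - 1))] & v > v[c(2:n, 1)])
  expect_identical(n_max, 3L)
})

test_that("project_to_series round-trips and isolates basis functions", {
  set.seed(4)
  s <- fourier_series(runif(1), runif(10, -1, 1) / (1:10), runif(10, -1, 1) / (1:10))
  w <- fourier_waveform(s, 200)
  s2 <- project_to_series(w, 10)
  expect_equal(s2$a0, s$a0, tolerance = 1e-10)
  expect_equal(s2$a, s$a, tolerance = 1e-10)
  expect_equal(s2$b, s$b, tolerance = 1e-10)

  flat <- sampled_waveform(rep(2.5, 64), period = 1, units = "au")
  sf <- project_to_series(flat, 10)
  expect_equal(sf$a0, 2.5, tolerance = 1e-12)
  expect_lt(max(abs(c(sf$a, sf$b))), 1e-12)

  ph <- (0:199) / 200
  sine <- sampled_waveform(sin(2 * pi * ph), abscissa = ph, period = 1,
                           units = "au")
  ss <- project_to_series(sine, 10)
  expect_equal(ss$b[1], 1, tolerance = 1e-10)
  expect_lt(max(abs(c(ss$a0, ss$a, ss$b[-1]))), 1e-10)

  expect_error(project_to_series(sampled_waveform(rnorm(20), period = 1), 10),
               "2 n \\+ 1")
})

test_that("objective matches a brute-force double-loop L2 oracle", {
  out <- generate_ensemble(ensemble_spec(n_pulses = 40, seed = 2))
  ens <- out$ensemble
  mean_series <- project_to_series(ensemble_mean(ens), 10)
  target <- 71
  res <- representative_objective(mean_series, ens, alpha = 0, target_ri = target)
  u <- evaluate_series(mean_series, (0:199) / 200)
  expect_equal(unname(res["e_l2"]), brute_force_e_l2(ens, u), tolerance = 1e-12)
  # alpha = 0 switches the penalty off exactly
  expect_identical(unname(res["e"]), unname(res["e_l2"]))

  res_pen <- representative_objective(mean_series, ens, alpha = 100,
                                      target_ri = target)
  expect_equal(unname(res_pen["e"]),
               sqrt(res_pen[["e_l2"]]^2 + (100 * res_pen[["e_ri"]])^2),
               tolerance = 1e-12)
})

test_that("an ensemble of identical pulses is already at the optimum", {
  # a band-limited pulse lies exactly in the search space, so the projected
  # mean is the optimum and the line search stalls immediately
  s <- reference_radial_series()
  p <- fourier_waveform(s, 200)
  ens <- pulse_ensemble(list(p, p, p, p))
  target <- radial_ai(s, dense_n = 2000)$ai_percent
  fit <- minimize_representative(ens, alpha = 100, max_iters = 10,
                                 target_ri = target)
  expect_lt(fit$e_total, 1e-8)
  expect_true(all(diff(fit$trace$e) <= 0))

  # a non-band-limited pulse leaves only truncation error
  g <- two_gauss_pulse()
  ensg <- pulse_ensemble(list(g, g, g, g))
  proj <- project_to_series(ensemble_mean(ensg), 10)
  res <- representative_objective(proj, ensg, alpha = 0,
                                  target_ri = radial_ai(g)$ai_percent)
  expect_lt(res[["e_l2"]], 1e-2)
})

test_that("objective trace is monotone non-increasing across seeds", {
  for (seed in c(1, 5, 17)) {
    out <- generate_ensemble(ensemble_spec(n_pulses = 8, seed = seed))
    fit <- minimize_representative(out$ensemble, alpha = 100, max_iters = 20)
    expect_gt(fit$iterations, 0)
    expect_true(all(diff(fit$trace$e) <= 1e-15))
  }
})

test_that("with alpha = 0 the minimizer matches the projected ensemble mean", {
  out <- generate_ensemble(ensemble_spec(n_pulses = 10, seed = 8))
  ens <- out$ensemble
  proj <- project_to_series(ensemble_mean(ens), 10)
  e_proj <- representative_objective(proj, ens, alpha = 0, target_ri = 71)
  fit <- minimize_representative(ens, alpha = 0, max_iters = 60)
  expect_lt(abs(fit$e_total - e_proj[["e_l2"]]), 1e-6)
})

test_that("large alpha preserves the ensemble mean AI", {
  out <- generate_ensemble(ensemble_spec(n_pulses = 40, seed = 6))
  fit <- minimize_representative(out$ensemble, alpha = 100, max_iters = 150)
  expect_lt(abs(fit$ai_percent - fit$target_ri) / fit$target_ri, 1e-3)
})

test_that("final E_RI is non-increasing along an alpha sweep", {
  out <- generate_ensemble(ensemble_spec(n_pulses = 12, seed = 19))
  finals <- vapply(c(1, 10, 100, 1000), function(a) {
    minimize_representative(out$ensemble, alpha = a, max_iters = 40)$e_ri_percent
  }, numeric(1))
  expect_true(all(diff(finals) <= 1e-10))
})

test_that("AI detection failure inside the search is penalized, not fatal", {
  out <- generate_ensemble(ensemble_spec(n_pulses = 6, seed = 3))
  flat <- fourier_series(0.5, numeric(10), numeric(10))
  res <- representative_objective(flat, out$ensemble, alpha = 100,
                                  target_ri = 71)
  expect_true(is.na(res[["ai"]]))
  expect_equal(res[["e_ri"]], 10)
  expect_true(is.finite(res[["e"]]))
})
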