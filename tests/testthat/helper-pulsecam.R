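# Shared fixture builders; everything is generated in code.

# Two-bump Gaussian pulse with a known peak-height ratio (the true AI on a
# normalized scale, up to bump overlap and the near-zero baseline).
two_gauss_pulse <- function(h2 = 0.733, phases = c(0.15, 0.35), width = 0.05,
                            n = 200) {
  make_base_pulse("gaussians",
                  list(phases = phases, heights = c(1, h2), widths = width),
                  n = n)
}

# Independent brute-force oracle for the ensemble L2 misfit: explicit double
# loop with the wrap-around trapezoidal integral, no linear algebra shared
# with the implementation.
brute_force_e_l2 <- function(ensemble, u_vals) {
  m <- length(ensemble$pulses)
  total <- 0
  for (i in seq_len(m)) {
    r <- ensemble$pulses[[i]]$values - u_vals
    r2 <- c(r^2, r[1]^2)
    h <- 1 / length(r)
    acc <- 0
    for (j in seq_len(length(r))) {
      acc <- acc + (r2[j] + r2[j + 1]) / 2 * h
    }
    total <- total + acc
  }
  sqrt(total) / m
}

# Literal brute-force of the 1-based DFT over one period: y evaluated at
# phases m/N (periodic), explicit O(N^2) double loop.
brute_force_dft <- function(values, n_harmonics) {
  N <- length(values)
  y_at <- function(m) values[(m %% N) + 1] # y(m/N), with y(1) = y(0)
  vapply(0:n_harmonics, function(f) {
    acc <- 0 + 0i
    for (m in seq_len(N)) {
      acc <- acc + y_at(m) * exp(-2i * pi * f * m / N)
    }
    acc
  }, complex(1))
}

expect_waveform_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tol)
  expect_equal(a$abscissa, b$abscissa, tolerance = tol)
}
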