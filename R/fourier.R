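#' Truncated Fourier series of a periodic pulse
#'
#' Canonical form of the representative waveform:
#' `u(theta) = a0 + sum_k a_k cos(2 pi k theta) + b_k sin(2 pi k theta)`
#' on the normalized period `theta in [0, 1)`.
#'
#' @param a0 Constant term.
#' @param a Cosine coefficients `a_1..a_n`.
#' @param b Sine coefficients `b_1..b_n` (same length as `a`).
#' @return An object of class `fourier_series` with elements `a0`, `a`, `b`,
#'   `n`, `period` (always 1).
#' @examples
#' s <- fourier_series(0, a = c(1, 0), b = c(0, 0))
#' evaluate_series(s, c(0, 0.25, 0.5))
#' @export
fourier_series <- function(a0, a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (length(a) < 1) stop("series dimension must be >= 1", call. = FALSE)
  if (!all(is.finite(c(a0, a, b)))) stop("coefficients must be finite", call. = FALSE)
  structure(list(a0 = as.numeric(a0), a = a, b = b, n = length(a), period = 1),
            class = "fourier_series")
}

#' @export
print.fourier_series <- function(x, ...) {
  cat(sprintf("<fourier_series> n = %d harmonics, a0 = %.4g\n", x$n, x$a0))
  invisible(x)
}

# Coefficients as the flat vector (a0, a_1..a_n, b_1..b_n) and back.
#' @keywords internal
#' @noRd
series_to_coefs <- function(series) c(series$a0, series$a, series$b)

#' @keywords internal
#' @noRd
coefs_to_series <- function(coefs) {
  n <- (length(coefs) - 1) %/% 2
  fourier_series(coefs[1], coefs[2:(n + 1)], coefs[(n + 2):(2 * n + 1)])
}

# Design matrix of the truncated trigonometric basis at given phases;
# evaluate_series(s, ph) == fourier_basis(ph, n) %*% series_to_coefs(s).
#' @keywords internal
#' @noRd
fourier_basis <- function(phases, n) {
  k <- seq_len(n)
  ang <- outer(2 * pi * phases, k)
  cbind(1, cos(ang), sin(ang))
}

#' Evaluate a Fourier series at normalized phases
#'
#' Phases outside `[0, 1)` are wrapped (the series is periodic by
#' construction, so wrapping is exact).
#'
#' @param series A [fourier_series()].
#' @param phases Numeric vector of phases.
#' @return Numeric vector of waveform values.
#' @export
evaluate_series <- function(series, phases) {
  stopifnot(inherits(series, "fourier_series"))
  ph <- as.numeric(phases) %% 1
  drop(fourier_basis(ph, series$n) %*% series_to_coefs(series))
}

#' Sample a Fourier series as a waveform
#'
#' @param series A [fourier_series()].
#' @param n Number of uniform samples over one period (default 200).
#' @param units Units label for the result; the default `"au"` records that
#'   the series' own value scale is kept (no min-max rescaling).
#' @return A [sampled_waveform()].
#' @export
fourier_waveform <- function(series, n = 200, units = "au") {
  ph <- (seq_len(n) - 1) / n
  sampled_waveform(evaluate_series(series, ph), abscissa = ph, period = 1,
                   units = units)
}

#' Project a sampled waveform onto a truncated Fourier basis
#'
#' Least-squares trigonometric projection onto the `n`-harmonic basis. On a
#' uniform periodic grid the discrete basis functions are orthogonal, so the
#' projection reduces to the classical analysis sums and the reconstruction
#' error is orthogonal to the basis.
#'
#' @param waveform A [sampled_waveform()] on a uniform periodic grid with at
#'   least `2 n + 1` samples.
#' @param n Number of harmonics (default 10).
#' @return A [fourier_series()].
#' @export
project_to_series <- function(waveform, n = 10) {
  stopifnot(inherits(waveform, "sampled_waveform"))
  v <- waveform$values
  m <- length(v)
  if (m < 2 * n + 1) {
    stop("waveform length must be >= 2 n + 1 for an n-harmonic projection",
         call. = FALSE)
  }
  ph <- waveform_phases(waveform)
  k <- seq_len(n)
  ang <- outer(2 * pi * ph, k)
  a0 <- mean(v)
  a <- drop(crossprod(cos(ang), v)) * 2 / m
  b <- drop(crossprod(sin(ang), v)) * 2 / m
  fourier_series(a0, a, b)
}

#' Packaged representative radial-pulse Fourier coefficients
#'
#' The 21 coefficients (`a0`, `a_1..a_10`, `b_1..b_10`) of the built-in
#' representative radial pressure waveform of a healthy young adult, on the
#' published normalized-pressure scale (the waveform minimum is about 0.10,
#' not 0). Evaluated over one period the series has exactly three local
#' maxima -- percussion, late-systolic and dicrotic waves -- which is what
#' makes the corresponding cam a three-peak cam.
#'
#' @return A [fourier_series()] with 10 harmonics.
#' @examples
#' s <- reference_radial_series()
#' radial_ai(s)
#' @export
reference_radial_series <- function() {
  path <- system.file("extdata", "representative_radial_fourier.csv",
                      package = "pulsecam", mustWork = TRUE)
  tab <- utils::read.csv(path)
  ord <- order(tab$harmonic)
  tab <- tab[ord, ]
  stopifnot(tab$harmonic[1] == 0)
  fourier_series(tab$a[1], tab$a[-1], tab$b[-1])
}
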