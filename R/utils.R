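# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
wrap_deg <- function(x) {
  # wrap angles to (-180, 180]
  y <- ((x + 180) %% 360) - 180
  y[abs(y + 180) < 1e-12] <- 180
  y
}

# Mean-value quadrature of a periodic function sampled on a uniform grid over
# one period: equals the trapezoidal rule with the wrap-around point appended.
#' @keywords internal
#' @noRd
periodic_integral <- function(f_vals) {
  sum(f_vals) / length(f_vals)
}

# Parabolic (three-point quadratic) refinement of a discrete extremum.
# Returns c(offset, value): offset in grid steps from the centre sample.
#' @keywords internal
#' @noRd
parabolic_refine <- function(y_left, y_mid, y_right) {
  denom <- y_left - 2 * y_mid + y_right
  if (abs(denom) < .Machine$double.eps * (abs(y_mid) + 1)) {
    return(c(0, y_mid))
  }
  delta <- 0.5 * (y_left - y_right) / denom
  delta <- max(-0.5, min(0.5, delta))
  val <- y_mid - 0.25 * (y_left - y_right) * delta
  c(delta, val)
}

# Circular (wrap-around) local maxima / minima of a sampled period.
#' @keywords internal
#' @noRd
circular_local_maxima <- function(v) {
  n <- length(v)
  prev <- v[c(n, seq_len(n - 1))]
  nxt <- v[c(seq(2, n), 1)]
  which(v > prev & v >= nxt)
}

#' @keywords internal
#' @noRd
circular_local_minima <- function(v) {
  n <- length(v)
  prev <- v[c(n, seq_len(n - 1))]
  nxt <- v[c(seq(2, n), 1)]
  which(v < prev & v <= nxt)
}

# Centered moving average with periodic wrap; width forced odd.
#' @keywords internal
#' @noRd
circular_moving_average <- function(v, width) {
  width <- as.integer(width)
  if (width <= 1) return(v)
  if (width %% 2 == 0) width <- width + 1L
  half <- (width - 1L) %/% 2L
  n <- length(v)
  ext <- c(v[(n - half + 1):n], v, v[1:half])
  as.numeric(stats::filter(ext, rep(1 / width, width), sides = 2))[(half + 1):(half + n)]
}

# Savitzky-Golay smoothing on a periodic signal (wrap-padded).
#' @keywords internal
#' @noRd
circular_sgolay <- function(v, width, order = 3) {
  width <- as.integer(width)
  if (width %% 2 == 0) width <- width + 1L
  if (width <= order + 1) return(v)
  n <- length(v)
  half <- (width - 1L) %/% 2L
  ext <- c(v[(n - half + 1):n], v, v[1:half])
  sm <- signal::sgolayfilt(ext, p = order, n = width)
  sm[(half + 1):(half + n)]
}

# FNV-1a 32-bit hash of a character scalar, in pure double arithmetic.
# Used to fingerprint exported cam profiles.
#' @keywords internal
#' @noRd
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  two16 <- 65536
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% two16
    hi <- h %/% two16
    h <- (lo * p + ((hi * p) %% two16) * two16) %% two32
  }
  sprintf("%04x%04x", as.integer(h %/% two16), as.integer(h %% two16))
}

# XOR for doubles holding 32-bit unsigned values (bitwXor needs integers,
# which overflow above 2^31).
#' @keywords internal
#' @noRd
bitwXor_dbl <- function(a, b) {
  two31 <- 2147483648
  hi_a <- a %/% two31
  hi_b <- b %/% two31
  lo <- bitwXor(as.integer(a %% two31), as.integer(b %% two31))
  (hi_a + hi_b) %% 2 * two31 + lo
}
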