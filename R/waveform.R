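#' Sampled pressure waveform
#'
#' The universal currency between modules: one periodic pressure trace on a
#' uniform abscissa. The abscissa is either time in seconds (raw recordings)
#' or normalized phase on `[0, 1)` (period-normalized pulses).
#'
#' @param values Numeric vector of pressure samples (mmHg or normalized
#'   units). Must be finite.
#' @param abscissa Optional numeric vector of sample positions, strictly
#'   increasing and uniformly spaced (relative tolerance `1e-9`). When `NULL`,
#'   a uniform grid of `length(values)` points over one period is built,
#'   starting at 0, with the wrap-around sample excluded.
#' @param period Duration of one cycle in the abscissa's units. Defaults to
#'   `n * dt` for an explicit abscissa, or 1 for a phase grid.
#' @param units Free-text units label. `"normalized"` asserts min 0 / max 1
#'   (tolerance `1e-9`); `"au"` marks a dimensionless pressure scale that is
#'   not min-max scaled (e.g. a published normalized-pressure waveform whose
#'   minimum is not exactly zero).
#'
#' @return An object of class `sampled_waveform`: a list with elements
#'   `values`, `abscissa`, `period`, `units`.
#' @examples
#' w <- sampled_waveform(sin(2 * pi * (0:99) / 100), period = 0.8, units = "au")
#' w$period
#' @export
sampled_waveform <- function(values, abscissa = NULL, period = NULL,
                             units = "mmHg") {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("waveform needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values))) stop("waveform values must be finite", call. = FALSE)
  if (is.null(abscissa)) {
    if (is.null(period)) period <- 1
    abscissa <- (seq_len(n) - 1) / n * period
  } else {
    abscissa <- as.numeric(abscissa)
    if (length(abscissa) != n) {
      stop("abscissa and values lengths differ", call. = FALSE)
    }
    d <- diff(abscissa)
    if (any(d <= 0)) stop("non-monotone abscissa", call. = FALSE)
    dt <- mean(d)
    if (max(abs(d - dt)) > 1e-9 * max(abs(abscissa[n]), dt)) {
      stop("non-uniform sampling beyond tolerance", call. = FALSE)
    }
    if (is.null(period)) period <- n * dt
  }
  if (identical(units, "normalized")) {
    if (abs(min(values)) > 1e-9 || abs(max(values) - 1) > 1e-9) {
      stop("units 'normalized' requires min 0 and max 1", call. = FALSE)
    }
  }
  structure(
    list(values = values, abscissa = abscissa, period = period, units = units),
    class = "sampled_waveform"
  )
}

#' @export
print.sampled_waveform <- function(x, ...) {
  cat(sprintf(
    "<sampled_waveform> %d samples, period %.6g, units '%s', range [%.4g, %.4g]\n",
    length(x$values), x$period, x$units, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @keywords internal
#' @noRd
waveform_dt <- function(w) {
  if (length(w$abscissa) < 2) return(w$period)
  w$abscissa[2] - w$abscissa[1]
}

# Sample phases in [0, 1) relative to the waveform's own start.
#' @keywords internal
#' @noRd
waveform_phases <- function(w) {
  (w$abscissa - w$abscissa[1]) / w$period
}

#' Read a waveform from a delimited text file
#'
#' Expects at least two numeric columns (time in seconds, pressure); commas,
#' tabs, semicolons and whitespace all work as delimiters. A single header
#' line is detected and skipped; lines starting with `#` are comments.
#'
#' @param path Path to the file.
#' @param time_col,value_col Column indices of time and pressure (default 1, 2).
#' @param units Units label for the returned waveform.
#' @return A [sampled_waveform()] in raw units with a validated uniform
#'   abscissa.
#' @seealso [write_waveform()]
#' @export
read_waveform <- function(path, time_col = 1, value_col = 2, units = "mmHg") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no data rows in ", path, call. = FALSE)
  split_row <- function(s) strsplit(trimws(s), "[,;\t ]+")[[1]]
  first <- suppressWarnings(as.numeric(split_row(lines[idx[1]])))
  if (anyNA(first)) idx <- idx[-1] # header line
  if (length(idx) < 2) stop("fewer than 2 data rows in ", path, call. = FALSE)
  tv <- matrix(NA_real_, nrow = length(idx), ncol = 2)
  for (i in seq_along(idx)) {
    fields <- suppressWarnings(as.numeric(split_row(lines[idx[i]])))
    if (length(fields) < max(time_col, value_col) ||
        anyNA(fields[c(time_col, value_col)])) {
      stop(sprintf("non-numeric row at line %d of %s", idx[i], path),
           call. = FALSE)
    }
    tv[i, ] <- fields[c(time_col, value_col)]
  }
  sampled_waveform(tv[, 2], abscissa = tv[, 1], units = units)
}

#' Write a waveform to a delimited text file
#'
#' Emits comma-separated `time_s,pressure` rows at 15 significant digits, so
#' [read_waveform()] reads the waveform back losslessly to `1e-12`.
#'
#' @param waveform A [sampled_waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(waveform, path) {
  stopifnot(inherits(waveform, "sampled_waveform"))
  rows <- sprintf("%.15g,%.15g", waveform$abscissa, waveform$values)
  writeLines(c("time_s,pressure", rows), path)
  invisible(path)
}

#' Normalize a pulse to unit period and unit amplitude
#'
#' Maps the abscissa to phase on `[0, 1)` and min-max scales the values so the
#' diastolic foot sits at 0 and the systolic peak at 1. Idempotent on
#' already-normalized pulses.
#'
#' @param pulse A [sampled_waveform()]; must not be constant.
#' @return A normalized [sampled_waveform()] (`units = "normalized"`,
#'   `period = 1`).
#' @export
normalize_pulse <- function(pulse) {
  stopifnot(inherits(pulse, "sampled_waveform"))
  rng <- range(pulse$values)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    stop("degenerate input: constant pulse cannot be normalized", call. = FALSE)
  }
  v <- (pulse$values - rng[1]) / (rng[2] - rng[1])
  n <- length(v)
  sampled_waveform(v, abscissa = (seq_len(n) - 1) / n, period = 1,
                   units = "normalized")
}

#' Resample a pulse onto a uniform grid by periodic interpolation
#'
#' Treats the pulse as one full period with wrap-around (the sample at phase 1
#' equals the sample at phase 0) and interpolates onto `n` uniformly spaced
#' points. Linear interpolation is the default because it is monotone and
#' overshoot-free near the sharp systolic upstroke; a periodic cubic spline is
#' available for smooth waveforms where higher-order accuracy matters.
#'
#' @param pulse A [sampled_waveform()].
#' @param n Target number of samples (>= 16).
#' @param method `"linear"` (default) or `"spline"` (periodic cubic).
#' @return A [sampled_waveform()] with `n` samples, same period and units.
#' @export
resample_pulse <- function(pulse, n, method = c("linear", "spline")) {
  stopifnot(inherits(pulse, "sampled_waveform"))
  method <- match.arg(method)
  n <- as.integer(n)
  if (n < 16) stop("resample target n must be >= 16", call. = FALSE)
  ph <- waveform_phases(pulse)
  x <- c(ph, 1)
  y <- c(pulse$values, pulse$values[1])
  xout <- (seq_len(n) - 1) / n
  v <- if (method == "linear") {
    stats::approx(x, y, xout = xout, rule = 2)$y
  } else {
    stats::spline(x, y, method = "periodic", xout = xout)$y
  }
  units <- pulse$units
  if (identical(units, "normalized") &&
      (abs(min(v)) > 1e-9 || abs(max(v) - 1) > 1e-9)) {
    units <- "au" # interpolation can miss the exact extrema
  }
  sampled_waveform(v, abscissa = pulse$abscissa[1] + xout * pulse$period,
                   period = pulse$period, units = units)
}

#' Ensemble of period/amplitude-normalized pulses
#'
#' @param pulses List of normalized [sampled_waveform()]s sharing one common
#'   grid (all resampled to the same length and abscissa).
#' @param source_label Free-text provenance label.
#' @return An object of class `pulse_ensemble` with elements `pulses`,
#'   `grid_n`, `source_label`.
#' @export
pulse_ensemble <- function(pulses, source_label = "") {
  if (!is.list(pulses) || length(pulses) < 2) {
    stop("ensemble needs at least 2 pulses", call. = FALSE)
  }
  lens <- vapply(pulses, function(p) length(p$values), integer(1))
  if (length(unique(lens)) != 1) {
    stop("all ensemble pulses must share one grid length", call. = FALSE)
  }
  ref <- pulses[[1]]$abscissa
  for (p in pulses) {
    stopifnot(inherits(p, "sampled_waveform"))
    if (max(abs(p$abscissa - ref)) > 1e-9) {
      stop("all ensemble pulses must share one abscissa", call. = FALSE)
    }
  }
  structure(
    list(pulses = pulses, grid_n = lens[1], source_label = source_label),
    class = "pulse_ensemble"
  )
}

#' @export
print.pulse_ensemble <- function(x, ...) {
  cat(sprintf("<pulse_ensemble> %d pulses on a %d-point grid%s\n",
              length(x$pulses), x$grid_n,
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  invisible(x)
}

# Ensemble as a grid_n x M matrix (one column per pulse).
#' @keywords internal
#' @noRd
ensemble_matrix <- function(ensemble) {
  vapply(ensemble$pulses, function(p) p$values, numeric(ensemble$grid_n))
}

#' Pointwise mean pulse of an ensemble
#'
#' Arithmetic mean across pulses on the common grid; the classical averaged
#' waveform that serves as the initial guess of the representative-waveform
#' minimization.
#'
#' @param ensemble A [pulse_ensemble()].
#' @return A [sampled_waveform()] on the ensemble grid.
#' @export
ensemble_mean <- function(ensemble) {
  stopifnot(inherits(ensemble, "pulse_ensemble"))
  m <- rowMeans(ensemble_matrix(ensemble))
  p1 <- ensemble$pulses[[1]]
  units <- p1$units
  if (identical(units, "normalized") &&
      (abs(min(m)) > 1e-9 || abs(max(m) - 1) > 1e-9)) {
    units <- "au" # the mean of normalized pulses need not span [0, 1]
  }
  sampled_waveform(m, abscissa = p1$abscissa, period = p1$period, units = units)
}

#' Segment consecutive pulses from a continuous pressure record
#'
#' Detects diastolic feet as the local minimum preceding each steepest
#' systolic upstroke (maximum positive first difference) on a moving-average
#' smoothed copy of the record, then cuts the record foot-to-foot. Partial
#' pulses at the record edges are dropped.
#'
#' @param record A [sampled_waveform()] containing at least two full cycles,
#'   on a time abscissa.
#' @param min_period_s Minimum admissible pulse period in seconds (rejects
#'   double-detections within one upstroke).
#' @param smooth_frac Moving-average smoothing window as a fraction of the
#'   estimated period (default 0.05).
#' @param upstroke_frac Slope threshold for upstroke candidates, as a fraction
#'   of the maximum positive slope (default 0.5).
#' @return A list of [sampled_waveform()] pulses in raw units, foot-aligned
#'   and non-overlapping, with attributes `feet` (sample indices) and
#'   `periods_s`.
#' @export
segment_pulses <- function(record, min_period_s = 0.3, smooth_frac = 0.05,
                           upstroke_frac = 0.5) {
  stopifnot(inherits(record, "sampled_waveform"))
  v <- record$values
  n <- length(v)
  dt <- waveform_dt(record)
  amp <- diff(range(v))
  if (amp <= 1e-12 * max(1, abs(v[1]))) {
    stop("segmentation error: record is constant, no pulse feet detected",
         call. = FALSE)
  }
  min_sep <- max(2L, as.integer(round(min_period_s / dt)))

  locate_upstrokes <- function(sig) {
    d <- diff(sig)
    thr <- upstroke_frac * max(d)
    if (thr <= 0) return(integer(0))
    cand <- which(d >= thr)
    if (length(cand) == 0) return(integer(0))
    # keep the steepest sample of each run of above-threshold slopes
    ups <- integer(0)
    run_start <- cand[1]
    prev <- cand[1]
    for (i in cand[-1]) {
      if (i > prev + min_sep %/% 4) {
        seg <- run_start:prev
        ups <- c(ups, seg[which.max(d[seg])])
        run_start <- i
      }
      prev <- i
    }
    seg <- run_start:prev
    ups <- c(ups, seg[which.max(d[seg])])
    # enforce minimum separation, keeping the steeper of close pairs
    keep <- ups[1]
    for (u in ups[-1]) {
      if (u - keep[length(keep)] >= min_sep) {
        keep <- c(keep, u)
      } else if (d[u] > d[keep[length(keep)]]) {
        keep[length(keep)] <- u
      }
    }
    keep
  }

  # first pass on the raw record to estimate the period, second pass smoothed
  ups0 <- locate_upstrokes(v)
  est_period <- if (length(ups0) >= 2) stats::median(diff(ups0)) else n / 2
  win <- max(1L, as.integer(round(smooth_frac * est_period)))
  sm <- circular_moving_average(v, win)
  ups <- locate_upstrokes(sm)
  if (length(ups) < 2) {
    stop("segmentation error: fewer than 2 pulse feet detected", call. = FALSE)
  }

  feet <- integer(length(ups))
  for (k in seq_along(ups)) {
    j <- ups[k]
    while (j > 1 && sm[j - 1] < sm[j]) j <- j - 1
    # refine on the raw record in a small neighbourhood
    lo <- max(1L, j - win)
    hi <- min(n, j + win)
    feet[k] <- lo + which.min(v[lo:hi]) - 1L
  }
  feet <- unique(feet)
  if (length(feet) < 2) {
    stop("segmentation error: fewer than 2 pulse feet detected", call. = FALSE)
  }

  pulses <- vector("list", length(feet) - 1)
  for (k in seq_len(length(feet) - 1)) {
    idx <- feet[k]:(feet[k + 1] - 1L)
    pulses[[k]] <- sampled_waveform(v[idx], abscissa = record$abscissa[idx],
                                    period = length(idx) * dt,
                                    units = record$units)
  }
  attr(pulses, "feet") <- feet
  attr(pulses, "periods_s") <- diff(feet) * dt
  pulses
}
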