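#' Detect the early- and late-systolic peaks of a radial pulse
#'
#' Scans the pulse in its native phase order for local maxima within the
#' systolic window, prunes indistinct maxima (two maxima count as distinct
#' only when the trough between them lies at least `min_prominence` of the
#' full amplitude below the lower one), and refines peak position and height
#' by three-point parabolic interpolation. When no distinct second maximum
#' exists, the late-systolic shoulder is located from the first derivative:
#' the point where the post-peak downslope locally flattens (the local
#' maximum of the derivative between its local minimum and the next decay,
#' i.e. the inflection of the shoulder).
#'
#' @param pulse A [sampled_waveform()] (typically normalized) or a numeric
#'   vector of one period's samples.
#' @param systolic_end Late-peak search is restricted to phases below this
#'   bound (default 0.5) so the dicrotic wave is never mistaken for the
#'   late-systolic peak.
#' @param min_prominence Trough depth (fraction of full amplitude) required
#'   for two maxima to count as distinct (default 0.01).
#' @param smooth `"auto"` (default) applies periodic Savitzky-Golay smoothing
#'   only when high-frequency noise is detected; `"none"` never smooths;
#'   a number gives the smoothing window directly (samples).
#' @return A list with components `early` and `late` (each a list
#'   `(phase, value)`) and `foot_value`, the height reference: 0 on a clean
#'   normalized scale, or the smoothed waveform's minimum (a robust diastolic
#'   foot estimate) whenever noise-driven smoothing engages, so that additive
#'   corruption of the scale zero by noise cannot bias the peak heights.
#'   Phases are on the pulse's own `[0, 1)` grid and strictly increasing.
#' @export
detect_systolic_peaks <- function(pulse, systolic_end = 0.5,
                                  min_prominence = 0.01, smooth = "auto") {
  v <- if (inherits(pulse, "sampled_waveform")) pulse$values else as.numeric(pulse)
  n <- length(v)
  if (n < 16) stop("pulse too short for peak detection", call. = FALSE)
  amp <- diff(range(v))
  if (amp <= 0) stop("detection error: constant pulse", call. = FALSE)

  vs <- smooth_for_detection(v, amp, smooth)
  foot_value <- if (identical(vs, v)) 0 else min(vs)

  peaks <- prune_indistinct_maxima(vs, min_prominence * amp)
  refine <- function(i) {
    pr <- parabolic_refine(vs[if (i == 1) n else i - 1], vs[i],
                           vs[if (i == n) 1 else i + 1])
    list(phase = ((i - 1 + pr[1]) %% n) / n, value = pr[2])
  }
  cand <- lapply(peaks, refine)
  # window membership judged on refined phases: a discrete maximum sitting on
  # the wrap-around sample belongs at phase ~1, not 0
  cand <- cand[vapply(cand, function(p) p$phase < systolic_end, logical(1))]
  if (length(cand) == 0) {
    stop("detection error: no systolic maximum in the search window",
         call. = FALSE)
  }
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "phase"))]
  early <- cand[[1]]

  if (length(cand) >= 2) {
    late <- cand[[2]]
  } else {
    early_idx <- peaks[which.min(abs((peaks - 1) / n - early$phase))]
    late <- shoulder_from_derivative(vs, early_idx, systolic_end)
    if (is.null(late)) {
      stop("detection error: no late-systolic feature", call. = FALSE)
    }
  }
  if (late$phase <= early$phase) {
    stop("detection error: late-systolic feature precedes the early peak",
         call. = FALSE)
  }
  list(early = early, late = late, foot_value = foot_value)
}

#' @keywords internal
#' @noRd
smooth_for_detection <- function(v, amp, smooth) {
  n <- length(v)
  if (identical(smooth, "none")) return(v)
  width <- if (is.numeric(smooth)) {
    as.integer(smooth)
  } else {
    # robust high-frequency noise estimate from second differences (smooth
    # pulses have small curvature per sample; white noise inflates it by
    # sigma * sqrt(6))
    noise <- stats::median(abs(diff(v, differences = 2))) / (0.6745 * sqrt(6))
    if (noise > 0.002 * amp) max(7L, as.integer(round(0.05 * n))) else 0L
  }
  if (width >= 5) circular_sgolay(v, width, order = 3) else v
}

# Local maxima that survive the trough-distinctness rule: neighbouring
# maxima separated by a trough shallower than min_depth are merged (the
# higher one survives). Returns sample indices sorted in phase order.
#' @keywords internal
#' @noRd
prune_indistinct_maxima <- function(v, min_depth) {
  maxima <- circular_local_maxima(v)
  if (length(maxima) <= 1) return(maxima)
  n <- length(v)
  repeat {
    m <- length(maxima)
    if (m <= 1) break
    merged <- FALSE
    for (j in seq_len(m)) {
      i1 <- maxima[j]
      i2 <- maxima[if (j == m) 1 else j + 1]
      # trough between the two maxima (circular span)
      span <- if (i1 < i2) (i1:i2) else c(i1:n, 1:i2)
      trough <- min(v[span])
      lower <- min(v[i1], v[i2])
      if (trough > lower - min_depth) {
        drop_idx <- if (v[i1] <= v[i2]) j else (if (j == m) 1 else j + 1)
        maxima <- maxima[-drop_idx]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  sort(maxima)
}

# Inflection-based fallback: after the early peak the derivative is negative;
# a shoulder appears as an interior local minimum of the derivative followed
# by an interior local maximum (the downslope flattening). If the derivative
# overshoots zero at that maximum, the shoulder is really a shallow peak and
# its apex sits at the following downward zero crossing. Transitions smaller
# than 1e-4 of the amplitude (per sample) are floating-point ripple on flat
# tails, not shoulders, and are rejected.
#' @keywords internal
#' @noRd
shoulder_from_derivative <- function(v, early_idx, systolic_end) {
  n <- length(v)
  amp <- diff(range(v))
  d <- (v[c(seq(2, n), 1)] - v[c(n, seq_len(n - 1))]) / 2
  hi <- min(n, as.integer(ceiling(systolic_end * n)))
  if (early_idx + 3 > hi) return(NULL)
  win <- (early_idx + 1):hi
  dm <- d[win]
  m <- length(dm)
  if (m < 5) return(NULL)
  loc_min <- which(dm < c(Inf, dm[-m]) & dm <= c(dm[-1], Inf) &
                     seq_len(m) > 1 & seq_len(m) < m)
  for (i0 in loc_min) {
    if (i0 >= m - 1) next
    rest <- (i0 + 1):m
    dr <- dm[rest]
    mr <- length(dr)
    loc_max <- which(dr > c(-Inf, dr[-mr]) & dr >= c(dr[-1], Inf) &
                       seq_len(mr) < mr)
    if (length(loc_max) == 0) next
    i1 <- rest[loc_max[1]]
    if (dm[i1] - dm[i0] < 1e-4 * amp) next
    if (dm[i1] > 0) {
      down <- which(dm[i1:m] <= 0)
      if (length(down) == 0) next
      idx <- win[i1 + down[1] - 1]
    } else {
      idx <- win[i1]
    }
    return(list(phase = (idx - 1) / n, value = v[idx]))
  }
  NULL
}

#' Radial augmentation index of a pulse
#'
#' The radial augmentation index (AI) is the ratio of the late-systolic to
#' the early-systolic pulse pressure, times 100. Peak heights are measured on
#' the pulse's normalized pressure scale: raw (mmHg) pulses are min-max
#' normalized first, which maps the diastolic foot to 0, so heights are
#' foot-referenced; waveforms that already carry their own normalized scale
#' (`units` `"normalized"` or `"au"`) are used as given. Values above 100 are
#' legal (a dominant reflected wave) and flagged, not rejected.
#'
#' @param pulse A [sampled_waveform()], a [fourier_series()] (evaluated on a
#'   dense grid with analytic peak refinement), or a numeric vector treated
#'   as one period on a normalized scale.
#' @param systolic_end,min_prominence,smooth Passed to
#'   [detect_systolic_peaks()].
#' @param dense_n Grid size for evaluating a `fourier_series` input
#'   (default 2000).
#' @param ... Unused.
#' @return An object of class `radial_ai_result`: list with
#'   `early_peak_phase`, `early_peak_height`, `late_peak_phase`,
#'   `late_peak_height`, `ai_percent` and a logical `flagged` (`TRUE` when
#'   `ai_percent > 100`).
#' @examples
#' radial_ai(reference_radial_series())
#' @export
radial_ai <- function(pulse, ...) UseMethod("radial_ai")

#' @rdname radial_ai
#' @export
radial_ai.sampled_waveform <- function(pulse, systolic_end = 0.5,
                                       min_prominence = 0.01,
                                       smooth = "auto", ...) {
  v <- pulse$values
  if (!pulse$units %in% c("normalized", "au")) {
    v <- normalize_pulse(pulse)$values
  }
  ai_from_values(v, systolic_end, min_prominence, smooth)
}

#' @rdname radial_ai
#' @export
radial_ai.numeric <- function(pulse, systolic_end = 0.5, min_prominence = 0.01,
                              smooth = "auto", ...) {
  ai_from_values(as.numeric(pulse), systolic_end, min_prominence, smooth)
}

#' @rdname radial_ai
#' @export
radial_ai.fourier_series <- function(pulse, dense_n = 2000,
                                     systolic_end = 0.5,
                                     min_prominence = 0.01, ...) {
  w <- fourier_waveform(pulse, n = dense_n, units = "au")
  pk <- detect_systolic_peaks(w, systolic_end = systolic_end,
                              min_prominence = min_prominence, smooth = "none")
  # polish both peak locations on the analytic series
  polish <- function(p) {
    half <- 1 / dense_n
    opt <- stats::optimize(function(t) -evaluate_series(pulse, t),
                           lower = p$phase - half, upper = p$phase + half,
                           tol = 1e-12)
    list(phase = opt$minimum %% 1, value = -opt$objective)
  }
  build_ai_result(polish(pk$early), polish(pk$late), 0)
}

#' @keywords internal
#' @noRd
ai_from_values <- function(v, systolic_end, min_prominence, smooth) {
  pk <- detect_systolic_peaks(v, systolic_end = systolic_end,
                              min_prominence = min_prominence, smooth = smooth)
  build_ai_result(pk$early, pk$late, pk$foot_value)
}

#' @keywords internal
#' @noRd
build_ai_result <- function(early, late, foot_value = 0) {
  h_early <- early$value - foot_value
  h_late <- late$value - foot_value
  if (h_early <= 0 || h_late < 0) {
    stop("detection error: non-positive peak height on the normalized scale",
         call. = FALSE)
  }
  ai <- 100 * h_late / h_early
  structure(
    list(early_peak_phase = early$phase, early_peak_height = h_early,
         late_peak_phase = late$phase, late_peak_height = h_late,
         ai_percent = ai, flagged = ai > 100),
    class = "radial_ai_result"
  )
}

#' @export
print.radial_ai_result <- function(x, ...) {
  cat(sprintf(
    "<radial_ai_result> AI = %.2f%%%s\n  early peak: %.4g at phase %.4f\n  late peak:  %.4g at phase %.4f\n",
    x$ai_percent, if (x$flagged) " (flagged: > 100%)" else "",
    x$early_peak_height, x$early_peak_phase,
    x$late_peak_height, x$late_peak_phase
  ))
  invisible(x)
}

#' @export
format.radial_ai_result <- function(x, ...) sprintf("%.2f%%", x$ai_percent)
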