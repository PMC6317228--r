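#' Penalized objective of the representative-waveform fit
#'
#' Total error of a candidate series `u` against a pulse ensemble:
#' `E = sqrt(E_L2^2 + (alpha * E_RI)^2)`, where
#' `E_L2 = (1/M) * sqrt( sum_i integral (u_i - u)^2 dtheta )` over the `M`
#' ensemble pulses (periodic quadrature on the common grid), and `E_RI` is
#' the *relative* radial-AI error `|RI - RI(u)| / RI` of the candidate
#' against the ensemble's target AI. With `alpha = 0` the objective is the
#' plain L2 misfit; with `alpha` large it becomes a penalty problem that
#' preserves the ensemble's mean augmentation index.
#'
#' When peak detection fails on the candidate, `E_RI` is assigned a large
#' finite penalty (`ai_fail_penalty`, relative scale) so the line search can
#' retreat instead of crashing.
#'
#' @param series A [fourier_series()] candidate.
#' @param ensemble A [pulse_ensemble()].
#' @param alpha Penalty weight (on the scale where `E_L2` is a fraction and
#'   `E_RI` is a relative AI error).
#' @param target_ri Target AI in percent (the ensemble's mean per-pulse AI).
#' @param ai_dense_n Dense grid used to measure the candidate's AI.
#' @param ai_fail_penalty Relative `E_RI` assigned on detection failure
#'   (default 10, i.e. ten times the target).
#' @return Named numeric vector `c(e, e_l2, e_ri, ai)`; `e_ri` is the
#'   relative AI error as a fraction, `ai` the candidate's AI in percent
#'   (`NA` on detection failure).
#' @export
representative_objective <- function(series, ensemble, alpha, target_ri,
                                     ai_dense_n = 1024, ai_fail_penalty = 10) {
  stopifnot(inherits(series, "fourier_series"),
            inherits(ensemble, "pulse_ensemble"))
  U <- ensemble_matrix(ensemble)
  ph <- waveform_phases(ensemble$pulses[[1]])
  B <- fourier_basis(ph, series$n)
  Bd <- fourier_basis((seq_len(ai_dense_n) - 1) / ai_dense_n, series$n)
  obj <- objective_closure(U, B, Bd, alpha, target_ri, ai_fail_penalty)
  obj(series_to_coefs(series))
}

# Fast closure over precomputed design matrices; the inner loop of the
# minimizer. Returns function(coefs) -> c(e, e_l2, e_ri, ai).
#' @keywords internal
#' @noRd
objective_closure <- function(U, B, Bd, alpha, target_ri, ai_fail_penalty) {
  n_grid <- nrow(U)
  m <- ncol(U)
  function(coefs) {
    u <- drop(B %*% coefs)
    e_l2 <- sqrt(sum((U - u)^2) / n_grid) / m
    ai <- ai_dense_grid(drop(Bd %*% coefs), coefs = coefs)
    e_ri <- if (is.na(ai)) ai_fail_penalty else abs(target_ri - ai) / target_ri
    e <- sqrt(e_l2^2 + (alpha * e_ri)^2)
    c(e = e, e_l2 = e_l2, e_ri = e_ri, ai = ai)
  }
}

# AI of a dense-grid candidate evaluation: first two distinct maxima in the
# systolic window, parabolic height refinement, zero-referenced heights on
# the candidate's own (normalized) scale. When the series coefficients are
# supplied, each peak is polished by a few Newton steps on the analytic
# derivative, making the AI smooth in the coefficients and exact to machine
# precision. Returns NA on failure; never throws, because the optimizer must
# be able to retreat from bad candidates.
#' @keywords internal
#' @noRd
ai_dense_grid <- function(v, systolic_end = 0.5, min_prominence = 0.01,
                          coefs = NULL) {
  n <- length(v)
  amp <- diff(range(v))
  if (amp <= 0) return(NA_real_)
  peaks <- prune_indistinct_maxima(v, min_prominence * amp)
  if (length(peaks) < 2) return(NA_real_)
  ref <- vapply(peaks, function(i) {
    parabolic_refine(v[if (i == 1) n else i - 1], v[i],
                     v[if (i == n) 1 else i + 1])
  }, numeric(2))
  phase <- ((peaks - 1 + ref[1, ]) %% n) / n
  keep <- phase < systolic_end
  if (sum(keep) < 2) return(NA_real_)
  ord <- order(phase[keep])
  ph2 <- phase[keep][ord][1:2]
  h <- ref[2, keep][ord][1:2]
  if (!is.null(coefs)) {
    for (j in 1:2) {
      pol <- series_peak_newton(coefs, ph2[j], max_step = 1 / n)
      if (!is.null(pol)) h[j] <- pol
    }
  }
  if (h[1] <= 0 || h[2] < 0) return(NA_real_)
  100 * h[2] / h[1]
}

# Newton polish of a series maximum near theta0; returns the peak value, or
# NULL when the local curvature is unusable (degenerate flat peak).
#' @keywords internal
#' @noRd
series_peak_newton <- function(coefs, theta0, max_step, steps = 3) {
  nh <- (length(coefs) - 1) %/% 2
  a <- coefs[2:(nh + 1)]
  b <- coefs[(nh + 2):(2 * nh + 1)]
  k <- 2 * pi * seq_len(nh)
  th <- theta0
  for (s in seq_len(steps)) {
    ang <- k * th
    d1 <- sum(k * (-a * sin(ang) + b * cos(ang)))
    d2 <- sum(k^2 * (-a * cos(ang) - b * sin(ang)))
    if (!is.finite(d1) || !is.finite(d2) || d2 >= 0) return(NULL)
    th <- th + max(-max_step, min(max_step, -d1 / d2))
  }
  coefs[1] + sum(a * cos(k * th) + b * sin(k * th))
}

#' Fit a representative waveform by penalized minimization
#'
#' Minimizes the AI-penalized L2 objective (see
#' [representative_objective()]) over the `2 n + 1` coefficients of a
#' truncated Fourier series. The ensemble mean, projected onto the basis, is
#' the initial guess; each iteration takes a central finite-difference
#' gradient and a backtracking (Armijo) line search that accepts only
#' decreases, so the objective trace is monotone non-increasing by
#' construction. The routine is deterministic: all stochasticity lives in
#' the data, not the optimizer.
#'
#' @param ensemble A [pulse_ensemble()].
#' @param alpha Penalty weight (default 100; "sufficiently large" preserves
#'   the target AI).
#' @param max_iters Maximum accepted iterations (default 150).
#' @param n_harmonics Series dimension (default 10).
#' @param target_ri Target AI in percent. Default `NULL` computes the mean
#'   per-pulse radial AI of the ensemble.
#' @param tol Stop when the relative objective decrease falls below this
#'   (default 0: run until `max_iters` or the line search stalls).
#' @param fd_step Central finite-difference step per coefficient.
#' @param armijo,backtrack Armijo constant and backtracking factor.
#' @param ai_dense_n Dense grid for the candidate-AI measurement.
#' @param ai_fail_penalty See [representative_objective()].
#' @return An object of class `fit_result`: list with `series`
#'   ([fourier_series()]), `e_total`, `e_l2_percent`, `e_ri_percent`
#'   (relative AI error as a percentage), `e_ri_raw` (percentage points),
#'   `ai_percent`, `target_ri`, `alpha`, `iterations`, `converged`, and
#'   `trace` (a data frame with one row per accepted iteration:
#'   `e`, `e_l2`, `e_ri`, `ai`, `step`).
#' @examples
#' spec <- ensemble_spec(n_pulses = 8, seed = 1)
#' ens <- generate_ensemble(spec)
#' fit <- minimize_representative(ens$ensemble, alpha = 100, max_iters = 10)
#' fit$e_ri_percent
#' @export
minimize_representative <- function(ensemble, alpha = 100, max_iters = 150,
                                    n_harmonics = 10, target_ri = NULL,
                                    tol = 0, fd_step = 1e-6, armijo = 1e-4,
                                    backtrack = 0.5, ai_dense_n = 1024,
                                    ai_fail_penalty = 10) {
  stopifnot(inherits(ensemble, "pulse_ensemble"))
  if (is.null(target_ri)) {
    ais <- vapply(ensemble$pulses,
                  function(p) radial_ai(p)$ai_percent, numeric(1))
    target_ri <- mean(ais)
  }
  U <- ensemble_matrix(ensemble)
  ph <- waveform_phases(ensemble$pulses[[1]])
  B <- fourier_basis(ph, n_harmonics)
  Bd <- fourier_basis((seq_len(ai_dense_n) - 1) / ai_dense_n, n_harmonics)
  obj <- objective_closure(U, B, Bd, alpha, target_ri, ai_fail_penalty)

  coefs <- series_to_coefs(project_to_series(ensemble_mean(ensemble),
                                             n = n_harmonics))
  p <- length(coefs)
  cur <- obj(coefs)
  if (!is.finite(cur["e"])) {
    stop("optimization error: non-finite objective at the initial guess",
         call. = FALSE)
  }

  trace <- matrix(NA_real_, nrow = max_iters, ncol = 5,
                  dimnames = list(NULL, c("e", "e_l2", "e_ri", "ai", "step")))
  step0 <- 0.1
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    g <- numeric(p)
    for (j in seq_len(p)) {
      cp <- coefs; cp[j] <- cp[j] + fd_step
      cm <- coefs; cm[j] <- cm[j] - fd_step
      g[j] <- (obj(cp)["e"] - obj(cm)["e"]) / (2 * fd_step)
    }
    if (!all(is.finite(g))) {
      stop(sprintf("optimization error: non-finite gradient at iteration %d", it),
           call. = FALSE)
    }
    gnorm2 <- sum(g^2)
    if (gnorm2 == 0) { converged <- TRUE; break }

    t_step <- step0
    accepted <- FALSE
    for (ls in seq_len(60)) {
      cand <- coefs - t_step * g
      res <- obj(cand)
      if (is.finite(res["e"]) && res["e"] <= cur["e"] - armijo * t_step * gnorm2) {
        accepted <- TRUE
        break
      }
      t_step <- t_step * backtrack
    }
    if (!accepted) { converged <- TRUE; break }

    rel_dec <- (cur["e"] - res["e"]) / max(cur["e"], .Machine$double.eps)
    coefs <- cand
    cur <- res
    iters <- it
    trace[it, ] <- c(res[c("e", "e_l2", "e_ri", "ai")], t_step)
    step0 <- t_step * 2
    if (tol > 0 && rel_dec < tol) { converged <- TRUE; break }
  }

  trace <- as.data.frame(trace[seq_len(iters), , drop = FALSE])
  structure(
    list(series = coefs_to_series(coefs),
         e_total = unname(cur["e"]),
         e_l2_percent = unname(cur["e_l2"]) * 100,
         e_ri_percent = unname(cur["e_ri"]) * 100,
         e_ri_raw = unname(cur["e_ri"]) * target_ri,
         ai_percent = unname(cur["ai"]),
         target_ri = target_ri, alpha = alpha,
         iterations = iters, converged = converged, trace = trace),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    paste0("<fit_result> %d iterations (alpha = %g)\n",
           "  E = %.6g, E_L2 = %.4g%%, E_RI = %.4g%% (relative)\n",
           "  AI = %.4f%% vs target RI = %.4f%%\n"),
    x$iterations, x$alpha, x$e_total, x$e_l2_percent, x$e_ri_percent,
    x$ai_percent, x$target_ri
  ))
  invisible(x)
}
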