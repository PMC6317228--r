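---
title: "Designing a cam-based radial pulse simulator: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a cam-based radial pulse simulator: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsecam)
```

## The problem

Mechanical pulse simulators are used to calibrate wearable blood-pressure
sensors and to standardize pulse-diagnosis training: a rotating cam presses a
piston, the piston pressurizes air, and a silicone "artery" reproduces a
human radial pressure waveform at a commanded heart rate and pulse pressure.
The design question this package answers in software is: given an ensemble
of measured radial pulses, what single waveform should the cam encode, how is
that waveform turned into a polar cam profile, and how faithful is the
played-back pressure signal?

The pipeline has five computational stages, each a module of this package:

1. **Waveform handling** (`read_waveform()`, `segment_pulses()`,
   `normalize_pulse()`, `resample_pulse()`, `ensemble_mean()`): segment a
   continuous tonometry record foot-to-foot, normalize each pulse to unit
   period and unit amplitude, and average on a common grid.
2. **Radial augmentation index** (`radial_ai()`): the ratio of late- to
   early-systolic peak height, times 100 — the stiffness-related statistic
   the design must preserve.
3. **Representative waveform** (`minimize_representative()`): a penalized
   least-squares fit over a truncated Fourier basis that matches the
   ensemble in L2 while pinning the augmentation index to the ensemble mean.
4. **Cam synthesis and playback** (`waveform_to_cam()`,
   `simulate_pressure()`): one pulse period per revolution; a software
   surrogate plays the cam back at a commanded heart rate, pulse pressure
   and diastolic level, optionally through a first-order pneumatic lag.
5. **Phase-delay analysis** (`pulse_dft()`, `phase_delay()`): per-harmonic
   DFT amplitudes and phase angles comparing reference and simulated pulses.

A seed-deterministic synthetic generator (`generate_ensemble()`,
`generate_continuous_record()`) stands in for clinical recordings so that
every stage is testable against known ground truth.

## The representative-waveform model

Pulses are normalized to period 1 and amplitude `[0, 1]`. A candidate
representative waveform is a truncated Fourier series

$$u(\theta) = a_0 + \sum_{k=1}^{n}\big(a_k \cos 2\pi k\theta + b_k \sin 2\pi k\theta\big),
\qquad \theta \in [0, 1),$$

with $n = 10$ harmonics by default — enough to carry the three features of a
young-adult radial pulse (percussion peak, late-systolic shoulder, dicrotic
wave) without chasing noise. The fitted objective is

$$E(u) = \sqrt{E_{L^2}(u)^2 + \big(\alpha\, E_{RI}(u)\big)^2},$$

where, for $M$ ensemble pulses $u_i$ on a common grid,

$$E_{L^2}(u) = \frac{1}{M}\sqrt{\sum_{i=1}^{M} \int_0^1 (u_i - u)^2\, d\theta},
\qquad
E_{RI}(u) = \frac{|RI - RI(u)|}{RI},$$

$RI$ being the ensemble mean of the per-pulse radial augmentation index and
$RI(u)$ the candidate's. The plain ensemble mean washes out the
late-systolic shoulder (averaging over peak-phase variation), so its AI is
biased low; the penalty term restores it. $E_{RI}$ is used in *relative*
form so that $\alpha$ has a scale-free meaning; the fit result reports the
raw percentage-point error alongside.

Mean-value quadrature on the periodic grid (equivalent to the trapezoidal
rule with the wrap-around point) evaluates the integral.

### Optimization

The ensemble mean projected onto the basis is the initial guess — on a
uniform grid the discrete trigonometric basis is orthogonal, so the
projection is the exact least-squares solution of the unpenalized problem.
Each iteration then takes a central finite-difference gradient over the
$2n + 1$ coefficients (step $10^{-6}$) and a backtracking Armijo line search
(constant $10^{-4}$, factor $0.5$, initial step doubled after each success)
that accepts only decreases, so the objective trace is monotone by
construction. The AI term is piecewise-smooth in the coefficients (peak
identities can switch), which is why no analytic gradient is attempted; the
line search absorbs the kinks. Default iteration budget: 150.

The candidate's AI must be smooth and precise for this to converge tightly:
peaks are bracketed on a 1024-point evaluation of the series, refined by
three-point parabolic interpolation, then polished with Newton steps on the
analytic series derivative. If peak detection fails on a degenerate
candidate, $E_{RI}$ is set to a large finite penalty (10, on the relative
scale) so the line search retreats instead of crashing.

With $\alpha = 100$ (default; "large" on a scale where $E_{L^2}$ is a few
times $10^{-3}$) the stationary relative AI error is driven to $\sim 10^{-9}$
within 150 iterations on default synthetic ensembles, while $E_{L^2}$ stays
at the ensemble's intrinsic dispersion floor — the AI pin costs essentially
nothing in waveform fidelity. An $\alpha$ sweep (1, 10, 100, 1000) gives
non-increasing final $E_{RI}$, which the tests assert.

## The augmentation-index convention

The radial AI is *late-systolic pulse pressure / early-systolic pulse
pressure × 100*. Two conventions circulate: heights measured from the
diastolic foot, or peak values on the normalized pressure scale. On a
min-max-normalized pulse (foot = 0) they coincide. The packaged
representative coefficients, however, describe a waveform on a published
normalized scale whose minimum is 0.10, not 0; only peak *values* on that
scale reproduce the published AI of this waveform (73.3%, our dense-grid
evaluation gives 72.89%). `radial_ai()` therefore min-max normalizes raw
(mmHg) pulses — making heights foot-referenced and the result invariant to
affine transforms of the input — and takes dimensionless waveforms
(`units` `"normalized"` or `"au"`) on their own scale.

Peak selection scans local maxima in native phase order: the early peak is
the first distinct maximum, the late peak the next, both restricted to the
systolic window (phase < 0.5 by default) so the dicrotic wave is never
picked. Two maxima are *distinct* only when the trough between them drops at
least 1% of the full amplitude below the lower one; otherwise the
late-systolic feature is recovered from the first derivative (the local
flattening of the downslope — the shoulder's inflection), and a monotone
decay with no such feature is a detection error, not a guess.

### Noise robustness

Measurement noise corrupts both peak picking and the amplitude scale. When
the second-difference noise estimate exceeds 0.2% of the amplitude, the
detector smooths with a periodic Savitzky–Golay filter (order 3, window 5%
of the period) *and* references heights to the smoothed waveform's minimum
rather than the scale zero. The latter matters: the minimum of
noise-corrupted data underestimates the true foot (an extreme-value bias),
so a noisy min-max normalization silently shifts the zero and inflates the
AI by several tenths of a percentage point; the robust foot cancels this to
first order. With this estimator, the full pipeline closure — generate a
default 40-pulse ensemble, fit with large $\alpha$, compare the fitted AI
with the generator's logged mean — holds within 0.1 percentage points
across seeds.

Limitation: on pulses with a genuinely flat diastolic tail (for example, a
sparse sum of Gaussian bumps) the foot location is ill-defined at the noise
floor, and a residual AI measurement bias of a few tenths of a percentage
point remains. Physiological pulses, whose diastolic decay meets the next
upstroke in a V-shaped foot, do not suffer from this.

## Cam synthesis and playback

`waveform_to_cam()` maps the normalized period to 360° and waveform value to
radial lift: $r(\phi) = r_{\mathrm{base}} + s\, u(\phi/360°)$, with the cam
anchored so that 0° is the diastolic foot — rotating from 0° replays the
pulse from end-diastole. The geometry must satisfy
$r_{\mathrm{base}} > s > 0$ (no self-intersection); convexity is *not*
guaranteed and the export header says so, since pressure-angle and undercut
analysis is out of scope. Defaults: 3600 points (0.1°), base radius 20 mm,
stroke 5 mm — the published design does not state the fabricated geometry,
so these are configurable round numbers of machining-plausible size.
Follower kinematics are knife-edge (lift = radius − base radius, periodic
linear interpolation between grid points), making
waveform → cam → displacement the identity on the grid to $10^{-9}$.

`simulate_pressure()` is a deliberately minimal software surrogate of the
pneumatic rig, not a fluid model: the cam angle advances kinematically
(realized period is exactly 60/HR seconds), lift maps linearly onto
[diastolic, diastolic + pulse pressure], and an optional first-order lag
$y' = (p_0 - y)/\tau$ — integrated exactly for piecewise-linear input —
emulates the one qualitative effect of air compressibility worth modelling:
a softened upstroke and a positive phase delay. The lag is off by default
and clearly a surrogate; its phase at the fundamental matches the analytic
$\arctan(2\pi f \tau)$ within 0.3°, which is the property the tests pin.

## Phase-delay analysis

`pulse_dft()` computes
$S(f) = \sum_{m=1}^{N} y(m/N)\, e^{-2\pi i f m / N}$ with $N = 200$ by
default — a 1-based summation over samples at phases $1/N \ldots 1$. For a
periodic pulse ($y(1) = y(0)$) this equals the standard 0-based FFT of the
samples at phases $0 \ldots (N-1)/N$, which is how it is computed; the test
suite checks the identity against a literal $O(N^2)$ double loop. Phase
angles are `atan2(Im, Re)` in degrees wrapped to $(-180°, 180°]$, and the
delay at each harmonic is reference minus simulated, re-wrapped, so a
positive delay means the simulated waveform lags. Harmonics are counted on
the normalized single-pulse period; at 60 bpm harmonics 1 and 2 coincide
with 1 Hz and 2 Hz. The fundamental-harmonic delay is also reported as a
percentage of one 360° cycle (11.4° → 3.2%). Phases of bins with negligible
magnitude (below $10^{-12}$ of the total spectrum) are refused rather than
returned as noise.

## The synthetic generator

`generate_ensemble()` emulates the steady-state region of a tonometry
recording: `n_pulses` (default 40) perturbed copies of a base pulse —
either the packaged representative coefficients or a three-Gaussian pulse
(percussion at phase 0.15, shoulder at 0.35 with height 0.695 mimicking a
typical young-adult male AI, dicrotic wave at 0.60) — with:

* amplitude scale $\sim N(1, 2\%)$ — contact-pressure drift;
* late-peak height scale $\sim N(1, 3\%)$, applied through a narrow
  Gaussian bump at the late-peak phase (exact multiplicative control of the
  late peak, leaving the other features untouched);
* additive white noise, sd 0.01 normalized units — small enough that peak
  detection never fails at defaults;
* min-max renormalization, as the measurement pipeline would apply.

Every draw is logged, and each pulse's true (noise-free) AI is computed and
recorded, so the ensemble's mean AI is known ground truth.
`generate_continuous_record()` additionally draws per-pulse periods
$\sim N(0.9\,\mathrm{s}, 2\%)$ (a resting rate of ~67 bpm; 5% jitter in the
segmentation stress tests), anchors each pulse at its diastolic foot, and
concatenates them at 250 Hz, optionally behind a linear pressurization ramp
— the shape a robotic tonometry system records while it searches for the
optimal hold-down pressure.

What the generator does *not* emulate: baseline wander, motion artifacts,
arrhythmic beats, sensor-array channel selection, or any within-pulse shape
variability beyond the late-peak scale. Passing tests therefore demonstrate
correctness of the algorithms under controlled dispersion, not robustness
to every artifact of clinical data.

Dispersion calibration: with the default jitters the ensemble's intrinsic
L2 dispersion floor is ~0.1%. Published values from in vivo ensembles are
an order of magnitude larger (the raw clinical pulses behind them are not
available), so the fidelity tests assert the fitted $E_{L^2}$ against the
synthetic ensemble's own dispersion floor — the quantity the method
actually controls — rather than against an unreproducible number.

## Numerical choices, in one place

* **Interpolation**: periodic linear by default (monotone, no overshoot at
  the systolic upstroke); periodic cubic spline behind a switch for smooth
  waveforms where fourth-order accuracy matters.
* **Common grid**: 200 points per pulse, matching the DFT length.
* **Quadrature**: mean-value rule on the periodic grid (= trapezoid with
  wrap).
* **Peak refinement**: 3-point parabola on grids; Newton on the analytic
  derivative for series; `stats::optimize` in the user-facing series AI.
* **Foot detection** (segmentation): local minimum preceding the steepest
  upstroke, on a moving-average-smoothed copy (window 5% of the estimated
  period), refined on the raw record; partial boundary pulses dropped.
* **Degenerate inputs**: constant pulses are errors for normalization and
  detection; a constant waveform maps to a circular cam (zero lift);
  negligible-magnitude DFT bins refuse to report a phase; AI failure inside
  the optimizer is a finite penalty.
* **Determinism**: the optimizer is deterministic; all randomness lives in
  the generator and is seed-controlled.
* **Problem sizes** used by the test suite and acceptance script: 40-pulse
  ensembles at 200 grid points, 150 fit iterations, 2000-point dense grids
  for AI evaluation, 720–3600-point cam profiles — the sizes the method is
  designed for.

## A worked run

```{r example, eval = FALSE}
out <- generate_ensemble(ensemble_spec(n_pulses = 40, seed = 7))
fit <- minimize_representative(out$ensemble, alpha = 100, max_iters = 150)
fit

cam <- waveform_to_cam(fit$series, base_radius_mm = 20, stroke_mm = 5)
w <- simulate_pressure(cam, playback_config(heart_rate_bpm = 65,
                                            pulse_pressure_mmHg = 50,
                                            diastolic_mmHg = 80,
                                            duration_s = 32,
                                            lag_tau_s = 0.02))
played <- ensemble_mean(steady_state_extract(w, 30))
design <- sampled_waveform((cam$radii_mm - 20) / 5, period = 1,
                           units = "normalized")
phase_delay(design, normalize_pulse(played))
```
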