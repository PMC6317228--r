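# pulsecam

Design and validate cam-follower radial pulse simulators in software.

Mechanical pulse simulators — a motor-driven cam pressing a piston into an
air cylinder behind a silicone artery — are used to calibrate wearable
blood-pressure sensors and to train pulse diagnosis. Their central design
artifact is the cam profile: one revolution must encode one radial pulse
period, and the encoded waveform must preserve the clinically meaningful
features of the measured pulses it represents. `pulsecam` implements the
computational pipeline for that design and its validation:

* **Pulse handling** — read/write two-column (time, pressure) text records,
  segment a continuous tonometry record into foot-to-foot pulses, normalize
  each pulse to unit period and amplitude, and average on a common grid.
* **Radial augmentation index (AI)** — `radial_ai()` detects the early- and
  late-systolic peaks and reports
  `AI = late-systolic pulse pressure / early-systolic pulse pressure × 100 (%)`,
  the arterial-stiffness surrogate the design must preserve.
* **Representative waveform** — `minimize_representative()` fits a
  10-harmonic Fourier series `u(θ) = a0 + Σ a_k cos 2πkθ + b_k sin 2πkθ`
  to a pulse ensemble by minimizing

  ```
  E(u) = sqrt( E_L2(u)^2 + (α E_RI(u))^2 )
  E_L2(u) = (1/M) sqrt( Σ_i ∫ (u_i − u)^2 dθ )      (waveform misfit)
  E_RI(u) = |RI − RI(u)| / RI                        (relative AI error)
  ```

  with a finite-difference gradient and a monotone backtracking line
  search. The plain ensemble mean blurs the late-systolic shoulder and
  under-reports AI; the penalty (α = 100 by default) pins the fitted AI to
  the ensemble mean `RI` at essentially no L2 cost.
* **Cam synthesis** — `waveform_to_cam()` maps the normalized period onto
  360°, `r(φ) = base + stroke · u(φ/360°)`, anchored at the diastolic foot;
  `export_cam()` writes a machining-grade point table with a checksummed
  header.
* **Playback surrogate** — `simulate_pressure()` rotates the cam at a
  commanded heart rate and maps follower lift onto a commanded pulse
  pressure and diastolic level, optionally through a first-order lag
  emulating air-compressibility (`y' = (p0 − y)/τ`).
* **Phase-delay analysis** — `pulse_dft()` / `phase_delay()` compare
  reference and simulated pulses per harmonic (N = 200 DFT): amplitudes,
  phase angles, delay in degrees and as percent of one 360° cycle.
* **Synthetic ground truth** — `generate_ensemble()` /
  `generate_continuous_record()` produce seed-deterministic three-peak
  pulse ensembles and records (amplitude / late-peak / period jitter plus
  noise) with every pulse's true AI logged, so the whole pipeline is
  testable without clinical data.

The package ships the 21 Fourier coefficients of a representative
young-adult radial waveform (`reference_radial_series()`); evaluated over
one period it has exactly three local maxima — hence a "three-peak cam" —
and a radial AI of 72.9%.

## Worked example

From a synthetic 40-pulse steady-state ensemble to a validated playback:

```r
library(pulsecam)

out <- generate_ensemble(ensemble_spec(n_pulses = 40, seed = 7))
round(attr(out$log, "mean_ai_true"), 2)   # ground-truth mean AI: 71.52

fit <- minimize_representative(out$ensemble, alpha = 100, max_iters = 150)
fit
#> <fit_result> 150 iterations (alpha = 100)
#>   E = 0.000943012, E_L2 = 0.0943%, E_RI = 5.154e-09% (relative)
#>   AI = 71.4912% vs target RI = 71.4912%

cam <- waveform_to_cam(fit$series, base_radius_mm = 20, stroke_mm = 5)
cam
#> <cam_profile> 3600 points, base 20 mm, stroke 5 mm, radius range [20, 25] mm

w <- simulate_pressure(cam, playback_config(heart_rate_bpm = 65,
                                            pulse_pressure_mmHg = 50,
                                            diastolic_mmHg = 80,
                                            duration_s = 32,
                                            lag_tau_s = 0.02))
played <- ensemble_mean(steady_state_extract(w, 30))
round(radial_ai(normalize_pulse(played))$ai_percent, 2)   # 71.73

design <- sampled_waveform((cam$radii_mm - 20) / 5, period = 1,
                           units = "normalized")
phase_delay(design, normalize_pulse(played))
#> <phase_delay_report> N = 200
#>   harmonic 1: ref  -98.896 deg, sim -101.837 deg, delay    2.942 deg
#>   harmonic 2: ref -133.089 deg, sim -138.701 deg, delay    5.612 deg
#>   delay at harmonic 1 = 0.82% of one cycle
```

Reading the numbers: the fit preserves the ensemble's mean AI to ~5×10⁻⁹ %
relative error while the waveform misfit stays at the ensemble's dispersion
floor (0.09%); playing the cam back through a 20 ms pneumatic lag delays
the pulse by a positive ~2.9° at the fundamental (0.8% of a cycle) and
shifts the realized AI by ~0.2 points — small, and in the direction the
compressible working fluid predicts.

A command-line interface over the same functions is installed at
`inst/cli/pulsecam` (subcommands `segment`, `normalize`, `ai`,
`fit-representative`, `design-cam`, `simulate`, `phase-delay`, `synth`);
see `pulsecam --help`.

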