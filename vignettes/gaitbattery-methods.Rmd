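---
title: "Digital gait characteristics and PLS-DA classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital gait characteristics and PLS-DA classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbattery)
```

## What this package computes

A single tri-axial accelerometer worn on the lower back (L5) records
vertical (VT), mediolateral (ML) and anteroposterior (AP) acceleration
while a person walks.  When heel-strike and toe-off times are known —
in the laboratory they come from an instrumented walkway that the
person repeatedly crosses — the signal can be cut into straight-walk
passes, strides (heel strike to ipsilateral heel strike) and steps
(heel strike to contralateral heel strike), and a large battery of
*digital gait characteristics* can be computed from those segments.

`gaitbattery` implements a 210-characteristic battery organized in
five domains:

| domain          | n  | content |
|-----------------|----|---------|
| spatiotemporal  | 25 | means, SDs, left/right asymmetries, cadence and coefficients of variation of step/stride timings, lengths and velocities |
| frequency       | 56 | dominant-peak geometry of the Welch power spectral density, harmonic ratio, index of harmonicity, total power |
| regularity      | 20 | step/stride regularity from the unbiased autocorrelation, their ratio, and the gait symmetry index |
| magnitude       | 84 | RMS, SD, max, min, range, jerk RMS and jerk ratio per axis and per segmentation level |
| complexity      | 25 | phase-plot orbit geometry and largest Lyapunov exponents |

Six demographic/clinical covariates (age, sex, height, weight, BMI,
MoCA) complete a 216-column design matrix.  A from-scratch NIPALS
PLS-DA classifier with cross-validated component selection, Q²/R²X/R²Y
quality curves and VIP variable ranking is then trained on six nested
feature subsets (spatiotemporal and signal-based, each with and
without demographics, plus the full battery), and evaluated by pooled
out-of-fold accuracy, sensitivity, specificity and ROC AUC with the
Parkinson group as the positive class.

Because no clinical recordings ship with the package, a synthetic
cohort generator stands in for the study data.  It is a first-class,
tested component: every downstream stage is exercised end to end
against its known ground truth.

## The synthetic gait model

One subject is a walk over an oval circuit with repeated straight
passes (default 5–6 passes of 8 steps) separated by turns of 1.5–2.5 s
that carry no gait events and are never analysed.  Within a pass the
signal is a harmonic series on the stride cycle with stride phase
$\theta$ advancing $\pi$ per step:

* VT and AP carry *even* stride harmonics (the step frequency
  dominates, as in real lumbar accelerometry),
* ML carries *odd* stride harmonics (body sway alternates left/right
  with a full-stride period).

Each step $k$ has a duration $d_k = T_{step} + \varepsilon_k$
(timing jitter, $\varepsilon_k \sim N(0, \sigma_t^2)$) and an
amplitude factor combining multiplicative jitter (coefficient of
variation $c_a$) with a left/right asymmetry scaling
$1 \mp \alpha/2$.  In-band white noise models motor output
variability and is signal-dependent, scaling with the vigor of the
vertical movement (squared relative step length) — the standard
motor-control assumption that noise grows with signal amplitude.
Without it, a fixed noise floor would make every
signal-to-noise-sensitive characteristic (regularity, harmonicity,
local dynamic stability) a deterministic function of movement
amplitude, which the battery is precisely meant to measure as
*independent* information.  Gravity
($9.80665\,\mathrm{m/s^2}$) is added to VT, an optional static tilt
rotates the whole frame, and the ±8 g range of a typical wearable
sensor is emulated by clipping.

The dominant VT amplitude is not free: it is chosen so that double
integration of the VT component reproduces the vertical sensor
excursion $h$ that the inverted-pendulum relation
$L = 2\sqrt{2lh - h^2}$ (sensor height $l \approx 0.53 \times$ body
height) maps back to the subject's nominal step length.  Step-length
recovery by the pipeline is therefore a genuine closed loop and is
tested as such.

### Group structure of the default cohort

The default cohort holds 81 PD-like and 61 control-like subjects.
Control parameters are drawn from plausible older-adult values (stride
frequency 0.92 ± 0.045 Hz, step length 0.66 ± 0.05 m, timing jitter
12 ± 3 ms, ML/AP amplitude scale 1.00 ± 0.09, per-step amplitude CV
5 ± 1%, asymmetry 0.04 ± 0.02).  The PD-like group is shifted, in
control-SD units: ML/AP trunk amplitudes −1.5, step length −0.5
(which also lowers the vertical dynamics through the pendulum
relation), timing jitter +1.5, per-step amplitude CV +0.8, asymmetry
+0.8, cadence unchanged.  PD-like subjects complete 5 passes against 6
for controls, mirroring the slower circuit time of a slower walk.

This structure emulates the qualitative group differences the battery
is meant to detect — lower signal magnitudes (most strongly
mediolateral), lower regularity and harmonicity, shorter and slower
steps, higher step-length variability, higher Lyapunov exponent — with
the signal-based domains carrying more discriminative information than
the spatiotemporal domain alone.  Concentrating the amplitude effect
on ML/AP reflects the clinical picture of impaired trunk/postural
control; preserving cadence reflects the early-disease pattern of
shortened steps at a maintained rhythm.  Effect sizes are fixed design
choices of the generator, not fitted quantities; setting
`effect_scale = 0` yields a fully exchangeable null cohort (including
an identical pass count in both groups) for calibration checks.

What the generator does *not* emulate: freezing-of-gait episodes,
turning dynamics as analysable gait, sensor drift or miscalibration,
and any non-stationarity across the bout.  Passing tests therefore
demonstrate correctness of the *pipeline* under a controlled gait
model, not clinical performance on real recordings.

## Preprocessing and segmentation

Recordings are preprocessed once, identically for every feature
domain: (i) tilt correction rotating the mean acceleration vector onto
VT; (ii) subtraction of the gravity constant (the mean vector
magnitude) from VT; (iii) a 4th-order zero-phase low-pass Butterworth
filter at 20 Hz (applied forward–backward with `signal::filtfilt`).

Event times map to samples by rounding; all segments are half-open
0-based index intervals `[start, end)`, so steps tile strides and
strides tile passes exactly.  Passes with fewer than four heel strikes
are dropped with a warning — the weakest rule that still yields one
stride per foot.  Whether the source study filtered pass signals
before feature extraction is unstated; one fixed preprocessing
everywhere removes that degree of freedom.

## Numerical choices worth knowing

* **Welch PSD**: Hann window, 3 s segments, 50% overlap, per-segment
  linear detrend, one-sided density scaled so its integral equals the
  signal variance (checked against Parseval within 2%).  The dominant
  peak (0.3–5 Hz) is refined by parabolic interpolation through the
  three top bins, and half-power bounds are interpolated linearly, so
  peak frequency, width and slope vary continuously rather than
  snapping to the 1/3 Hz bin grid.
* **Harmonic ratio**: finite Fourier amplitudes at harmonics 1–20 of
  the stride frequency; even/odd amplitude ratio for VT and AP,
  odd/even for ML; capped at 10^6 when the denominator vanishes.  The
  index of harmonicity uses power at the fundamental (stride frequency
  for ML, step frequency for VT/AP) over the cumulative power of the
  first six harmonics.
* **Autocorrelation**: the unbiased estimator
  $A(m) = \frac{1}{N-m}\sum_i x_i x_{i+m}$, normalized by $A(0)$ and
  restricted to lags $\le N/2$ where its variance stays bounded.  Step
  and stride regularity are peak values within ±20% of the nominal
  lags, which tolerates timing jitter without locking onto neighbouring
  harmonics.  The gait symmetry index combines the three per-axis
  autocorrelations at the step lag as
  $\mathrm{GSI} = \lVert (A_{VT}, A_{ML}, A_{AP}) \rVert / \sqrt 3$;
  the *unbiased* form is used so that perfectly periodic gait scores
  exactly 1 (the biased estimator caps at $(N-m)/N$ by construction).
* **Magnitude**: all measures on mean-removed segment samples (with
  gravity and slow drift already removed, per-segment mean removal
  prevents residual offsets from dominating VT).  The resultant axis
  is the Euclidean norm of the mean-removed axes, which makes
  $RMS_{res}^2 = RMS_{VT}^2 + RMS_{ML}^2 + RMS_{AP}^2$ an exact
  identity.  Jerk is the central-difference derivative; the jerk ratio
  is the dimensionless smoothness `jerk RMS × duration / RMS`.
* **Phase plots**: one orbit per stride in the plane of z-normalized
  acceleration against z-normalized jerk.  Orbit area uses the
  shoelace formula; half-orbit asymmetries split the orbit along its
  principal axes (closed-form 2 × 2 PCA) by Sutherland–Hodgman
  clipping, giving quantities invariant to rotation and uniform
  scaling by construction.  An acceleration–derivative orbit (rather
  than a delay plot) is the convention under which "long half orbit
  area asymmetry" is well defined.
* **Largest Lyapunov exponent**: the Rosenstein algorithm — delay
  embedding (dimension 5; delay at the first minimum of the average
  mutual information, fallback 10 samples), nearest neighbours outside
  a Theiler window of one mean stride, least-squares slope of the mean
  log-divergence over the first half stride, reported per second.  The
  joint three-axis variant embeds each axis in dimension 2 and
  concatenates the coordinates.  The estimator is validated against an
  independent two-trajectory (Benettin-style) divergence oracle on a
  Lorenz trajectory, to within 20%.
* **Degenerate inputs** return missing values with a logged message
  (all-zero PSD input, zero-RMS jerk ratio, vertical excursion
  exceeding sensor height, orbits with zero area), and hard errors
  where silence would corrupt results (events outside the recording,
  constant signals in the autocorrelation, zero-variance predictor
  columns named explicitly).

## PLS-DA, component selection and VIP

The class matrix is one-hot (PD, CL) and column-centered; predictors
are median-imputed (training medians) and autoscaled.  Components are
extracted by NIPALS with deflation of both blocks; convergence is a
relative score change below 1e-10 (at most 500 iterations — with a
two-column response convergence is effectively immediate).  At full
rank the fit coincides with ordinary least squares, which the tests
exploit as an oracle.

Predictive quality uses stratified 7-fold cross-validation (the fold
scheme is a design choice; the source protocol is unstated) with
autoscaling refit inside every training fold:
$Q^2(a) = 1 - \mathrm{PRESS}(a)/\mathrm{SS}(Y)$, alongside cumulative
$R^2X$ and $R^2Y$ from the full-data fit.  The number of components is
the smallest $a$ whose $Q^2$ gain falls below 0.01 (capped at 10) — an
explicit plateau rule standing in for "determined on cross-validation
performance".  Class predictions take the argmax of the two continuous
outputs, ties resolving to PD.

VIP at component $a$ is the cumulative form
$\mathrm{VIP}_j(a) = \sqrt{p \sum_{b \le a} SSY_b w_{jb}^2 / \sum_{b \le a} SSY_b}$,
whose squared values average to 1 across features at every $a$;
features are ranked by the average VIP over the model's components
(the alternative reading — averaging per-component increments — is not
used).  Battery metrics are computed on pooled out-of-fold predictions
by default, with a held-out-split mode available, since the source
protocol for its reported metrics is ambiguous; group statistics use
Welch's t-test and z-scores against the control distribution, with
Benjamini–Hochberg adjustment available but off by default (the
convention being raw p < 0.05 flags).

## Problem sizes used in the checks

The test suite verifies structure exactly (210 = 25 + 56 + 20 + 84 +
25 features; 216 design columns), the math core against independent
oracles (brute-force autocorrelation, Mann–Whitney AUC, OLS at full
rank, VIP normalization, Monte-Carlo polygon areas, a Lorenz
divergence oracle), and the statistical behaviour on replicate
cohorts: 20 planted-effect cohorts at the full study size (81 + 61)
for effect-direction and model-ordering checks, and 20 null cohorts of
40 subjects for chance-level calibration — the null battery's sampling
error at that size is well below the ±10-percentage-point band being
checked, so the reduced size trades no statistical resolution away.
Single-subject recordings are ~35 s of 100 Hz data (5–6 mat passes
with turns), matching the pass/step counts of the emulated protocol.

## Known limitations

* The harmonic gait model has no stride-to-stride correlation
  structure (jitter is white), so long-range variability measures
  would be uninformative on it; none are included in the battery.
* The inverted-pendulum step length integrates the vertical
  acceleration within each turn-free pass; integration drift is
  removed by a 0.1 Hz 4th-order zero-phase high-pass on segments long
  enough to support it (more than about three cutoff periods) and by
  linear detrending otherwise — typical passes take the detrend path.
  The uncorrected canonical estimator is the default and the empirical
  1.25 calibration factor is exposed as an option.
* Whole-bout ("bout") level features include the synthetic turn
  segments; regularity and spectral values at that level are therefore
  systematically lower than their pass-level counterparts.  Group
  contrasts are unaffected because the protocol is identical within
  group.
* The Lyapunov exponent of ~35 s bouts is a short-series estimate;
  it is treated as a relative (between-group) measure, not an absolute
  dynamical invariant.
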