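---
title: "Validating insole pressure sensors against a force plate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating insole pressure sensors against a force plate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insoleGRF)
```

## Scope

`insoleGRF` implements a complete measurement-validation pipeline for a
two-sensor pressure-sensing insole (IPS) estimating resultant ground
reaction force (GRF) against a force-plate (FP) reference, together with a
synthetic gait generator that stands in for human-subject recordings. This
vignette explains the models, the tunable parameters, the numerical
choices, and what passing the test suite does and does not demonstrate
about real data.

## The synthetic gait model

**Stance waveform.** Each gait cycle's stance phase (62% of the stride) is
an "M"-shaped resultant GRF built from three raised-cosine lobes: a
weight-acceptance lobe centred at 28% of stance, a push-off lobe at 72%
(both with half-width 0.28 stance units), and a midstance valley lobe at
50% (half-width 0.18). The lobe supports are chosen so that neither peak
lobe covers the other's centre and the valley lobe covers neither peak
centre; consequently the configured peak heights (defaults 110 and
105 %BW, valley contribution 75 %BW) are attained *exactly* at the peak
instants, which gives downstream peak-extraction tests an analytic truth.
Swing force is identically zero. Per-cycle peak heights are perturbed by
independent Gaussian draws (`peak_sd`, default 4 %BW in the pipeline) so
that the Bland–Altman magnitude axis has realistic spread; `peak_sd = 0`
gives bit-reproducible identical cycles for noise-free checks. Stride
period is `1.4 / sqrt(speed)` s, i.e. ~1.98, 1.40 and 1.14 s at the three
protocol speeds (0.5, 1.0, 1.5 m/s) — typical of slow-to-brisk treadmill
walking.

**Regional partitioning.** Within each stance run the total force is
split as a raised-cosine cross-fade from hindfoot-dominant loading at
contact to forefoot-dominant loading at toe-off, with a constant fraction
`region_share_mid` (default 0.12) routed through the unsensed midfoot.
The decomposition conserves force exactly at every sample by
construction.

**Sensor law.** Each sensor's conductance is affine-quadratic in the
force it sees: `1/R = 1/R0 + g1 F + g2 F²`, so resistance decreases
strictly monotonically from the unloaded baseline `R0`. Defaults
(`R0` = 5000/5600 ohm, `g1` ≈ 2e-6 /(ohm N), `g2` ≈ 1.5e-9 /(ohm N²))
put the loaded range at roughly 600–5000 ohm over 0–1 BW, giving ~30
points on the 150-ohm calibration grid. The quadratic conductance term
matters: it makes the *inverse* map (force as a function of conductance)
close to, but not exactly, a quadratic polynomial, so the calibration
family fits well without being trivially exact. Drift is a linear
additive trend on resistance (default 0.5 ohm/s) and measurement noise is
additive Gaussian resistance noise (default SD 20 ohm); neither is
quantified by published hardware data, so both are exposed as
`sensor_model()` parameters.

**Coverage and the implied total-force coefficients.** Each sensor
captures a fraction `true_coverage_*` of its region's force. Because a
step calibration trial routes the subject's entire weight through one
region (the FP reads `F`, the sensor sees `coverage × F`), the per-sensor
quadratic absorbs coverage, and the calibrated sensor channel estimates
*regional* force directly. The coefficients of the scaled-sum total-force
model are therefore pulled toward `1/(1 − region_share_mid)` ≈ 1.14 for
both sensors, and land near 1.2 in practice because the heavy insole
smoothing (below) attenuates insole peaks and the peak-level fit
compensates. Both effects are realistic reasons why such coefficients
exceed 1, and the fitted values sit inside the 0.69–2.33 (hind) and
0.71–1.38 (fore) ranges observed for real subjects.

**Trial timeline.** A 30-s walking trial holds 60,000 FP samples at
2,000 Hz: a quiet lead-in, a 0.2-s stomp transient at t = 2 s with
amplitude 180 %BW (at least 30 %BW above any walking peak, and above the
1.5× median-walking-peak detection threshold), and continuous gait from
t = 4 s. The insole clock ticks at a nominal 28 Hz with uniform ±10%
period jitter — reproducing a 28 ± 1.2 Hz empirical rate — and is offset
from the FP clock by a configurable constant to emulate unsynchronized
acquisition. All truth (heel strikes, per-cycle peaks, stomp time, clock
offset) is retained on the trial object.

**What the generator does not emulate.** Hysteresis in the sensor law,
temperature effects, strap-tightness changes to the unloaded baseline,
electrode degradation, inter-step variation in foot placement on the
sensor, non-stationary drift, and the correlation structure of real
biological gait variability. Passing tests therefore demonstrate that the
*analysis chain* is correct and self-consistent under a plausible data
model — not that a physical sensor meets any accuracy figure.

## Signal conditioning

- **Resampling.** Irregular insole records are interpolated onto a
  uniform 2,000 Hz grid with a cubic spline. Walking GRF content lies
  almost entirely below 10 Hz (the test suite checks ≥ 99% of spectral
  energy), comfortably under the 14 Hz source Nyquist, and spline
  reconstruction of a 5 Hz tone sampled at ~28 Hz is accurate to well
  under 1% RMS. A Hamming-window FIR anti-aliasing low-pass (cutoff at
  90% of the target Nyquist) is applied only when the target rate is
  below the source rate.
- **Binomial smoothing.** The insole channel is smoothed by the exact
  binomial kernel equivalent to 10,000 passes of (1, 2, 1)/4 — kernel
  `dbinom(0:(2n), 2n, 1/2)`, variance `n/2` samples², sigma ≈ 70.7
  samples ≈ 35 ms at 2,000 Hz — applied by FFT convolution with
  edge-replication padding (unit DC gain). The naive repeated-pass
  formulation is kept as a test reference on short signals; the two agree
  exactly beyond `n` samples from the record edges, where the padding
  convention is immaterial.
- **FP filtering.** 4th-order Butterworth low-pass at 20 Hz, applied
  forward–backward (zero phase) so event and peak timings are not lagged.
  Zero-phase filtering squares the magnitude response; a single-pass
  option is retained (`phase = "single"`), for which the textbook
  40 Hz attenuation `1/sqrt(1 + (40/20)^8)` ≈ 0.0624 is asserted in the
  tests.
- **Zeroing.** Drift moves the unloaded resistance level, which maps to a
  spurious force offset after calibration. Trials are zeroed by
  subtracting the mean *calibrated force* over unloaded spans
  (resistance within 2% of the trial maximum), i.e. zeroing operates on
  force after calibration; the generic `zero_baseline()` also accepts
  explicit windows. Residual swing noise is then clamped to exactly zero
  on the unloaded mask.

## Gait events

Stomp synchronization matches two fiducials: on the FP, the time of
maximum force slope just before the first crossing of 1.5× the median
walking peak; on the insole, the steepest drop within the first 5 s
measured on the conductance (1/R) scale with parabolic sub-sample
refinement. The conductance scale matters: resistance falls fastest near
zero load (|dR/dF| is maximal there), so a raw-resistance fiducial sits
systematically ~30 ms early, while conductance is locally proportional to
force and lands at the transient's maximum force slope. Residual
synchronization error on synthetic trials is ~10 ms, well under one
insole sample period (~36 ms).

Heel strikes use each instrument's native rule: FP, first upward crossing
of 20 N preceded by at least 0.1 s below threshold (the debounce is not
part of the published rule but prevents double counts on noisy
crossings); insole, the first sample of any span with resistance below
98% of baseline lasting at least 0.25 s. The insole rule is applied to
the conditioned (post-filter) resistance. Cycles are the half-open
intervals between consecutive FP heel strikes after the stomp; both
instruments are peak-extracted inside the same FP-defined windows once
synchronized, with instrument-specific peak rules.

## Calibration

Loading phases are extracted automatically (the original protocol did
this manually): force peaks with prominence above 20 %BW delimit the
steps, and each phase runs from the start of the last contiguous loaded
run (force > 2 %BW of body weight *and* resistance below 98% of baseline)
up to its peak. A ramp still rising at the end of the record counts as
peaking at the final sample. Each phase is regridded at exactly 150-ohm
resistance spacing (forces linearly interpolated), which weights the fit
uniformly in resistance rather than dwell time; spans smaller than one
grid step fall back to the segment endpoints with a warning. The pooled
pairs feed an ordinary least-squares quadratic of force on conductance.
Degenerate inputs are handled explicitly: fewer than three distinct
conductances is an error, an all-zero response returns zero coefficients
with `r2 = NaN` and a warning, and a non-monotone fitted curve over the
fitted range warns.

The total-force fit has *no intercept* — zero sensor force must map to
zero total force — and is solved by `lm.fit` on the per-cycle peak rows
pooled across all trials of the calibration fold (all speeds in one fit).
Collinear hind/fore columns are an error. Applying a calibration to
another subject's signal is rejected by an id check; resistances outside
the fitted range are flagged as extrapolations rather than rejected,
since walking forces legitimately exceed the body-weight calibration
ceiling.

## Agreement analysis

Differences are fixed as insole minus FP, so negative bias means the
insole under-reads. `2S = 1.96 × SD` of the differences holds to machine
precision by construction, and the bias-vs-magnitude regression uses the
pair mean as abscissa (standard Bland–Altman practice). A one-sample
two-sided t-test of MoD against zero treats cycles as independent. When
the error sits on one instrument only, regressing differences on pair
means has a small structural slope `var(d)/2 / var(mean)` even with no
true magnitude trend; the test suite asserts this value rather than
zero.

The stratified two-fold cross-validation enumerates all `2³ = 8`
assignments of one trial per speed to the calibration fold, refits the
total-force scaling per iteration, and evaluates both assessments on the
complementary fold. Insole cycles with fewer than two peaks wider than
0.05 s (width at half prominence) are dropped from the two-peak
assessment only and counted. The representative iteration maximizes the
overlap coefficient (integral of the pointwise minimum of densities)
between its implied normal `N(MoD_i, (2S_i/1.96)²)` and the mean-level
normal, with ties broken to the lowest index; the overlap coefficient
was chosen as a concrete operationalization of "most overlapping
distribution", and the degenerate zero-variance case is defined as
overlap 1 for identical point masses and 0 otherwise.

## PWB simulation and its oracle

True maximum forces are `F ~ N(50, 25²)` %BW; the measurement is
`M = F + D` with `D | F ~ N(s·F + b, σe²)` taken from the fitted
regression (slope `s`, intercept `b`, residual SD `σe`). The regression
line is applied to the *true* force even though it was fitted against
pair means; the difference is second order in the error and documented
here rather than corrected. Overload means strictly greater than the
limit; values exactly at the limit (measure zero) classify as below, a
convention stated for bit-reproducibility. Sensitivity is the fraction of
truly-below-limit forces classified below; specificity the fraction of
truly-above-limit forces classified above.

Because `(F, M)` is bivariate normal — means `(μ, (1+s)μ + b)`, SDs
`(σf, sqrt((1+s)²σf² + σe²))`, covariance `(1+s)σf²` — both rates have
closed forms in the bivariate normal CDF. `pbvnorm()` evaluates the
tetrachoric single-integral representation by adaptive quadrature
(`rel.tol 1e-13`), is validated against brute-force conditional-normal
integration, and handles `ρ = ±1` and the deterministic `σe = 0` limits
explicitly. The Monte-Carlo engine must agree with this oracle within
three binomial standard errors in every tested configuration; when an
observed error count is zero the plug-in SE collapses, so the oracle
rate supplies the binomial SE instead.

## Problem sizes and runtime choices

The test suite exercises the full protocol (six 30-s trials, 60,000 FP
samples each) once, and otherwise uses 8–16-s trials and reduced PWB draw
counts (1e4–1e6) for pipeline mechanics, determinism and bias checks;
oracle-equivalence checks run at the protocol's full n = 1e7 draws. These
sizes were chosen so the whole suite completes in a few minutes while
still covering the protocol-scale code paths at least once.

## Known limitations

- The pipeline's absolute agreement numbers (MoD ≈ +0.7 %BW,
  2S ≈ 4–5 %BW on default synthetic subjects) characterize the synthetic
  model, not any physical sensor; real-subject values are several-fold
  wider and vary strongly across feet and sensors.
- With a constant midfoot share the two total-force coefficients are
  nearly equal by construction; differentiating them would require a
  midfoot share correlated with one region's loading.
- Automated loading-phase extraction assumes clean ramp trials; heavily
  corrupted calibration data will fail loudly rather than recover.
- The insole heel-strike rule's time resolution is one insole sample
  (~36 ms); cycle-level metrics inherit that jitter.
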