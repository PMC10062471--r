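# insoleGRF

Validation tooling for estimating resultant ground reaction force (GRF)
during walking from a low-cost, two-sensor pressure-sensing insole (IPS),
benchmarked against a laboratory force plate (FP).

## The problem

Force plates are the reference instrument for measuring GRF, but they are
expensive and fixed in place. A wearable insole with piezoresistive fabric
sensors under the hindfoot and forefoot can estimate GRF anywhere — if its
resistance signals can be calibrated to force and if the resulting
measurement error is characterized well enough to trust it for clinical
uses such as partial weight bearing (PWB), where a patient's peak limb
load must stay under a prescribed fraction of body weight (BW).

This package implements the full validation pipeline for such a system,
driven by a synthetic gait generator with known ground truth so that every
stage is testable without human recordings:

1. **Synthetic gait** — double-peaked ("M"-shaped) stance waveforms at
   0.5/1.0/1.5 m/s, regional force partitioning (hindfoot / unsensed
   midfoot / forefoot), a monotone sensor law
   `R(F) = 1/(1/R0 + g1 F + g2 F²)` with drift and noise, step calibration
   trials (three 0 → BW → 0 ramps), jittered ~28 Hz insole clocks, and a
   stomp transient for synchronization.
2. **Signal conditioning** — spline resampling of irregular insole records
   to 2,000 Hz, a 10,000-pass binomial smoother (Gaussian-equivalent,
   sigma ≈ 35 ms), a zero-phase 4th-order 20 Hz Butterworth filter for the
   FP, baseline force zeroing over unloaded spans, and swing clamping.
3. **Gait events** — stomp-based clock synchronization, heel-strike
   detection (FP: first crossing of 20 N; IPS: resistance below 98% of
   baseline for at least 0.25 s), and cycle segmentation.
4. **Calibration** — per-sensor least-squares quadratic of force on
   conductance, `F = a0 + a1 G + a2 G²` with `G = 1/R`, fitted on loading
   phases gridded every 150 ohm; then the scaled-sum total-force model

   `F_total = C_hind · F_hind + C_fore · F_fore`

   fitted without intercept on the per-cycle FP peak forces, which
   accounts for the unsensed midfoot (the implied midfoot force is
   `(C_hind − 1) F_hind + (C_fore − 1) F_fore`).
5. **Agreement** — per-cycle two-peak (2PK) and maximum (MAX) force
   extraction from both instruments and Bland–Altman analysis: mean of
   differences (MoD), `2S = 1.96 SD` of differences, limits of agreement
   `MoD ± 2S`, and a bias-vs-magnitude regression — inside a stratified
   two-fold cross-validation (one trial per speed per fold, all 8 splits).
6. **PWB simulation** — maximum forces `F ~ N(50, 25²)` %BW corrupted by
   the fitted error model and classified against a 50 %BW limit; reports
   sensitivity and specificity by Monte Carlo (n = 10⁷) and by an exact
   bivariate-normal closed form that serves as a zero-variance oracle.

## Worked example

```r
library(insoleGRF)
subject <- subject_model(subject_id = "S01")   # 75.2 kg, two sensors
res <- run_pipeline(subject, run_config(seed = 7L, pwb_n = 1e6))
print(res)
```

```
<pipeline_result>
 assessment  mod_mean    mod_sd two_s_mean  two_s_sd
      twopk 0.6575925 0.3510587   4.420444 0.1576220
        max 0.6300313 0.3628061   4.809597 0.1019439
  representative iteration: 4
  total-force coefficients (all trials): 1.234, 1.197
<pwb_result> sensitivity = 1.0000 (SE 0), specificity = 0.5090 (SE 0.00071)
```

Reading this: across the 8 cross-validation iterations the insole
over-reads the FP by ~0.7 %BW on average (MoD) in both assessments, with
limits of agreement about ±4.4–4.8 %BW around that bias (2S). The
total-force coefficients near 1.2 scale the two sensor channels up to
cover the unsensed midfoot (and the smoothing losses of the slow insole
clock). The PWB block then says: with this error model a truly
under-limit load is essentially never flagged as overload
(sensitivity 1.00), while just over half of true overloads are caught
(specificity 0.51) — the synthetic sensor's bias is conservative at the
50 %BW boundary. The per-sensor fits themselves are strong:

```r
print(res$sensor_cals$hind)
#> <sensor_calibration> F = -121.9 + 6.494e+05 G + -9.254e+07 G^2 (G = 1/R), r2 = 0.9993
#>   fitted over R in [610, 4510] ohm
```

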