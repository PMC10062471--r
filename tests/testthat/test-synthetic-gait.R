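test_that("waveform generator honours the empty case and exact peak heights", {
  s <- default_subject()
  empty <- generate_grf_waveform(1.0, 0, s)
  expect_length(empty$grf, 0)
  expect_length(empty$hs_times, 0)

  # the continuous stance shape attains the configured heights exactly at
  # the peak instants (the lobe supports exclude each other's centres)
  expect_equal(insoleGRF:::stance_shape(0.28, 110, 105, 75), 110,
               tolerance = 1e-12)
  expect_equal(insoleGRF:::stance_shape(0.72, 110, 105, 75), 105,
               tolerance = 1e-12)
  wav <- generate_grf_waveform(1.0, 5, s, peaks = c(110, 105), peak_sd = 0)
  pbw <- wav$grf$values * 100 / s$body_weight
  # the sampled maximum sits at most half a sample's curvature below
  expect_lte(max(pbw), 110 + 1e-9)
  expect_gt(max(pbw), 110 - 1e-4)
  expect_error(generate_grf_waveform(-1, 3, s), "positive")
  expect_error(generate_grf_waveform(1, 2.5, s), "integer")
})

test_that("heel-strike truth marks the first 20 N exceedance of each cycle", {
  s <- default_subject()
  wav <- generate_grf_waveform(1.0, 6, s, peak_sd = 0)
  fs <- 2000
  for (hs in wav$hs_times) {
    i <- which(wav$grf$timestamps >= hs)[1]
    expect_gt(wav$grf$values[i], 20)
    expect_lte(wav$grf$values[max(1, i - 2)], 20)  # crossing, not dwell
  }
  # between consecutive heel strikes the force returns to zero (swing)
  mins <- vapply(seq_len(5), function(k) {
    sel <- wav$grf$timestamps > wav$hs_times[k] &
      wav$grf$timestamps < wav$hs_times[k + 1]
    min(wav$grf$values[sel])
  }, numeric(1))
  expect_equal(mins, rep(0, 5))
})

test_that("regional decomposition conserves force and orders the peaks", {
  s <- default_subject()
  wav <- generate_grf_waveform(1.0, 4, s, peak_sd = 0)
  reg <- decompose_regional_forces(wav$grf, s)
  total <- reg$hind$values + reg$mid$values + reg$fore$values
  expect_equal(total, wav$grf$values)
  expect_equal(reg$mid$values, s$region_share_mid * wav$grf$values)

  # hindfoot dominates the first peak, forefoot the second
  pbw <- wav$grf$values * 100 / s$body_weight
  i1 <- which.max(ifelse(wav$grf$timestamps < wav$hs_times[1] + 0.4,
                         pbw, -Inf))
  i2 <- which.max(ifelse(wav$grf$timestamps > wav$hs_times[1] + 0.4 &
                           wav$grf$timestamps < wav$hs_times[2], pbw, -Inf))
  expect_gt(reg$hind$values[i1], reg$fore$values[i1])
  expect_lt(reg$hind$values[i2], reg$fore$values[i2])

  no_mid <- subject_model(region_share_mid = 0)
  reg0 <- decompose_regional_forces(wav$grf, no_mid)
  expect_equal(reg0$mid$values, rep(0, length(wav$grf)))

  bad <- sampled_signal(c(0, 1), c(-1, 0), "N")
  expect_error(decompose_regional_forces(bad, s), "non-negative")
})

test_that("the sensor law is monotone, anchored at R0, and invertible", {
  sens <- sensor_model(drift_rate = 0, noise_sd = 0)
  t <- seq(0, 10, length.out = 200)
  zero <- sampled_signal(t, rep(0, 200), "N")
  expect_equal(force_to_resistance(zero, sens, noise = FALSE)$values,
               rep(sens$baseline_resistance, 200))

  f <- sampled_signal(t, seq(0, 900, length.out = 200), "N")
  r <- force_to_resistance(f, sens, noise = FALSE)
  expect_true(all(diff(r$values) < 0))
  expect_true(all(r$values <= sens$baseline_resistance))

  back <- resistance_to_force(r, sens)
  expect_equal(back$values, f$values, tolerance = 1e-9)

  bad <- sampled_signal(c(0, 1), c(0, Inf), "N")
  expect_error(force_to_resistance(bad, sens), "finite")
})

test_that("calibration trials contain the protocol's three body-weight steps", {
  s <- default_subject()
  tr <- generate_calibration_trial(s, "hind", seed = 11, noise = FALSE)
  v <- tr$fp_force$values
  pk <- insoleGRF:::find_peaks(v, min_prominence = 0.2 * s$body_weight)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$height, rep(s$body_weight, 3), tolerance = 1e-9)

  # identical seed, identical trial
  tr2 <- generate_calibration_trial(s, "hind", seed = 11, noise = FALSE)
  expect_identical(tr, tr2)
  tr3 <- generate_calibration_trial(s, "hind", seed = 12, noise = TRUE)
  expect_false(identical(tr$ips_resistance$values,
                         tr3$ips_resistance$values))

  # minimum resistance corresponds to the sensor seeing coverage * BW
  law_min <- 1 / (1 / s$hind_sensor$baseline_resistance +
                    s$hind_sensor$conductance_gain *
                    s$body_weight * s$true_coverage_hind +
                    s$hind_sensor$conductance_curvature *
                    (s$body_weight * s$true_coverage_hind)^2)
  # drift can only raise resistance; sampling may miss the exact peak
  expect_equal(min(tr$ips_resistance$values), law_min,
               tolerance = 5e-3)
})

test_that("walking trials match the acquisition protocol", {
  wt <- clean_trial()
  expect_length(wt$fp_force, 60000)
  expect_equal(wt$fp_force$nominal_rate, 2000)
  rate <- 1 / mean(diff(wt$ips_hind$timestamps))
  expect_gt(rate, 28 - 1.2)
  expect_lt(rate, 28 + 1.2)
  expect_identical(wt$truth$clock_offset, 0.37)
  # swing-phase force is exactly zero in noise-free mode
  expect_true(any(wt$fp_force$values == 0))
  # the stomp tops every walking peak by a wide margin
  walking <- wt$fp_force$values[wt$fp_force$timestamps > 3]
  stomp <- max(wt$fp_force$values[wt$fp_force$timestamps < 3])
  expect_gt(stomp, max(walking) + 0.3 * wt$subject$body_weight)
  expect_error(generate_walking_trial(default_subject(), 0.7),
               "speed must be one of")
})

test_that("generated GRF is essentially band-limited below 10 Hz", {
  wt <- clean_trial()
  sel <- wt$fp_force$timestamps > 4   # walking only, stomp excluded
  x <- wt$fp_force$values[sel]
  x <- x - mean(x)
  spec <- Mod(stats::fft(x))^2
  n <- length(x)
  freq <- (seq_len(n) - 1) * 2000 / n
  half <- freq <= 1000
  below10 <- freq <= 10
  expect_gt(sum(spec[half & below10]) / sum(spec[half]), 0.99)
})

test_that("generators are pure functions of configuration and seed", {
  s <- default_subject()
  a <- generate_walking_trial(s, 1.5, seed = 9, duration = 10)
  b <- generate_walking_trial(s, 1.5, seed = 9, duration = 10)
  expect_identical(a, b)
  c <- generate_walking_trial(s, 1.5, seed = 10, duration = 10)
  expect_false(identical(a$ips_hind$values, c$ips_hind$values))
})
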