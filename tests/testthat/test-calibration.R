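test_that("loading-phase extraction finds the three ramps", {
  s <- default_subject()
  tr <- generate_calibration_trial(s, "hind", seed = 21, noise = FALSE)
  phases <- extract_loading_phases(tr)
  expect_length(phases, 3)
  for (ph in phases) {
    # each segment ends at its step's force maximum (body weight)
    expect_equal(ph$F[nrow(ph)], max(ph$F))
    expect_equal(max(ph$F), s$body_weight, tolerance = 1e-3)
    # loading only: resistance decreases overall
    expect_lt(ph$R[nrow(ph)], ph$R[1])
  }

  # a monotone ramp ends at the global maximum
  t <- seq(0, 10, by = 5e-4)
  f <- s$body_weight * (t / 10)^2
  r_t <- seq(0, 10, by = 1 / 28)
  rv <- 5000 - 400 * r_t
  mono <- structure(
    list(fp_force = sampled_signal(t, f, "N"),
         ips_resistance = sampled_signal(r_t, rv, "ohm"),
         region = "hind", subject = s, n_steps = 1),
    class = "calibration_trial")
  ph <- extract_loading_phases(mono)[[1]]
  expect_equal(ph$F[nrow(ph)], max(f[t <= max(r_t)]), tolerance = 1e-3)

  mono$n_steps <- 3
  expect_error(extract_loading_phases(mono), "expected 3 loading steps")
})

test_that("resistance-grid downsampling uses an exact 150-ohm lattice", {
  # span of 1500 ohm -> 11 grid points
  R <- seq(6000, 4500, length.out = 200)
  F <- seq(0, 700, length.out = 200)
  out <- uniform_resistance_downsample(R, F, step = 150)
  expect_equal(nrow(out), 11)
  expect_equal(unique(round(diff(out$R), 9)), -150)
  # linear R(t), F(t): interpolation is exact
  expect_equal(out$F, approx(R, F, xout = out$R)$y, tolerance = 1e-12)

  expect_warning(small <- uniform_resistance_downsample(
    c(5000, 4990), c(0, 10), step = 150), "span")
  expect_equal(nrow(small), 2)
})

test_that("the quadratic conductance fit recovers exact coefficients", {
  G <- seq(2e-4, 1.5e-3, length.out = 30)
  F <- 2 + 3 * G + 4 * G^2
  cal <- fit_sensor_polynomial(data.frame(R = 1 / G, F = F))
  expect_equal(cal$a0, 2, tolerance = 1e-6)
  expect_equal(cal$a1, 3, tolerance = 1e-6)
  expect_equal(cal$a2, 4, tolerance = 1e-6)
  expect_equal(cal$r2, 1, tolerance = 1e-12)

  # degenerate all-zero response
  expect_warning(flat <- fit_sensor_polynomial(
    data.frame(R = 1 / G, F = 0 * G)), "zero variance")
  expect_equal(c(flat$a0, flat$a1, flat$a2), c(0, 0, 0), tolerance = 1e-12)
  expect_true(is.nan(flat$r2))

  expect_error(fit_sensor_polynomial(data.frame(R = c(1, 1, 1),
                                                F = c(0, 1, 2))),
               "distinct conductance")
})

test_that("noise-free sensor calibration is nearly perfect, noisy is strong", {
  cals <- clean_cals()
  expect_gt(cals$hind$r2, 0.99)
  expect_gt(cals$fore$r2, 0.99)
  s <- default_subject()
  noisy <- calibrate_sensor(
    generate_calibration_trial(s, "hind", seed = 31, noise = TRUE))
  expect_gt(noisy$r2, 0.85)
  expect_lt(noisy$r2, 1)
})

test_that("applying a calibration inverts the sensor law within 2 %BW", {
  s <- default_subject()
  cal <- clean_cals()$hind
  sens <- s$hind_sensor
  # noiseless, drift-free loading from 0 to BW through the true law
  f_true <- seq(0, s$body_weight, length.out = 400)
  drift_free <- sensor_model(sens$baseline_resistance,
                             sens$conductance_gain,
                             sens$conductance_curvature,
                             drift_rate = 0, noise_sd = 0)
  seen <- sampled_signal(seq(0, 399) / 28,
                         f_true * s$true_coverage_hind, "N")
  r <- force_to_resistance(seen, drift_free, noise = FALSE)
  f_hat <- apply_sensor_calibration(r, cal)
  err_pbw <- (f_hat$values - f_true) * 100 / s$body_weight
  expect_lt(max(abs(err_pbw)), 2)

  # constant resistance gives constant force
  const <- sampled_signal(c(0, 1, 2), rep(3000, 3), "ohm")
  expect_equal(length(unique(apply_sensor_calibration(const, cal)$values)),
               1L)

  # unloaded resistance maps close to zero force; the quadratic's
  # approximation error concentrates at the unloaded end of the range
  unloaded <- sampled_signal(0, cal$r_max, "ohm")
  f0 <- apply_sensor_calibration(unloaded, cal)$values
  expect_lt(abs(f0) * 100 / s$body_weight, 5)

  expect_error(apply_sensor_calibration(
    sampled_signal(c(0, 1), c(-5, 100), "ohm"), cal), "positive")
})

test_that("calibrations refuse to cross subjects", {
  cal <- clean_cals()$hind
  other <- sampled_signal(c(0, 1), c(4000, 3000), "ohm",
                          subject_id = "someone-else")
  expect_error(apply_sensor_calibration(other, cal), "someone-else")
})

test_that("the total-force fit recovers exact scaled-sum rows", {
  set.seed(6)
  fh <- runif(40, 100, 800)
  ff <- runif(40, 100, 800)
  rows <- data.frame(F_fp = 1.2 * fh + 0.9 * ff, F_hind = fh, F_fore = ff)
  cal <- fit_total_force(rows)
  expect_equal(cal$c_hind, 1.2, tolerance = 1e-9)
  expect_equal(cal$c_fore, 0.9, tolerance = 1e-9)

  plain <- data.frame(F_fp = fh + ff, F_hind = fh, F_fore = ff)
  cal1 <- fit_total_force(plain)
  expect_equal(c(cal1$c_hind, cal1$c_fore), c(1, 1), tolerance = 1e-9)

  collin <- data.frame(F_fp = c(1, 2, 3), F_hind = c(1, 2, 3),
                       F_fore = c(2, 4, 6))
  expect_error(fit_total_force(collin), "collinear")
  expect_warning(fit_total_force(
    data.frame(F_fp = 10 * fh + 0.9 * ff, F_hind = fh, F_fore = ff)),
    "plausible range")
})

test_that("total and midfoot force obey the defining identities", {
  t <- seq(0, 1, by = 0.01)
  fh <- sampled_signal(t, 100 * (1 + sin(t)), "N")
  ff <- sampled_signal(t, 50 * (1 + cos(t)), "N")
  cal <- structure(list(c_hind = 1.5, c_fore = 1.2),
                   class = "total_force_calibration")
  tot <- total_force(fh, ff, cal)
  mid <- estimate_midfoot(fh, ff, cal)
  # midfoot + raw sum == total, exactly
  expect_equal(mid$values + fh$values + ff$values, tot$values)
  # worked numbers: C = (1.5, 1.2), F = (100, 50) -> midfoot 60
  i <- 1
  expect_equal((1.5 - 1) * 100 + (1.2 - 1) * 50, 60)
  one <- structure(list(c_hind = 1, c_fore = 1),
                   class = "total_force_calibration")
  expect_equal(total_force(fh, ff, one)$values, fh$values + ff$values)
  expect_equal(estimate_midfoot(fh, ff, one)$values, rep(0, length(t)))
  # linearity in each argument
  fh2 <- sampled_signal(t, 2 * fh$values, "N")
  expect_equal(total_force(fh2, ff, cal)$values,
               tot$values + 1.5 * fh$values)
})
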