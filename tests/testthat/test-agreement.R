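# build one synthetic gait cycle: M-shaped force with peaks at 25% / 75%
make_cycle <- function(pk1 = 110, pk2 = 105, fs = 2000, dur = 1.2,
                       spike = NULL) {
  t <- seq(0, dur, by = 1 / fs)
  u <- t / dur
  v <- pk1 * insoleGRF:::raised_cosine(u, 0.25, 0.2) +
    pk2 * insoleGRF:::raised_cosine(u, 0.75, 0.2) +
    70 * insoleGRF:::raised_cosine(u, 0.5, 0.15)
  if (!is.null(spike)) {
    v <- v + spike[2] * insoleGRF:::raised_cosine(t, spike[1],
                                                  spike[3] / 2)
  }
  list(t = t, v = v)
}

test_that("force-plate peak rule splits the cycle at 30%", {
  cyc <- make_cycle()
  pk <- extract_2pk(cyc$t, cyc$v, "fp")
  expect_equal(pk$pk1, 110, tolerance = 1e-9)
  expect_equal(pk$pk2, 105, tolerance = 1e-9)
  expect_lt(pk$t1, pk$t2)
  expect_equal(pk$t1 / 1.2, 0.25, tolerance = 1e-3)
  expect_equal(pk$t2 / 1.2, 0.75, tolerance = 1e-3)
})

test_that("insole peak rule keeps the two largest wide peaks", {
  # three wide peaks: 110, 105 and a 60 midstance bump
  cyc <- make_cycle()
  cyc$v <- cyc$v - 70 * insoleGRF:::raised_cosine(cyc$t / 1.2, 0.5, 0.15) +
    60 * insoleGRF:::raised_cosine(cyc$t / 1.2, 0.5, 0.15)
  pk <- extract_2pk(cyc$t, cyc$v, "ips")
  expect_equal(sort(c(pk$pk1, pk$pk2)), c(105, 110), tolerance = 1e-6)
  expect_lt(pk$t1, pk$t2)

  # a towering but 0.02-s-wide spike is rejected by the width rule
  spiky <- make_cycle(spike = c(0.5, 150, 0.02))
  pk2 <- extract_2pk(spiky$t, spiky$v, "ips")
  expect_equal(sort(c(pk2$pk1, pk2$pk2)), c(105, 110), tolerance = 1e-6)

  # fewer than two qualifying peaks: flagged with NAs
  single <- make_cycle(pk2 = 0)
  single$v <- 110 * insoleGRF:::raised_cosine(single$t / 1.2, 0.5, 0.3)
  pk3 <- extract_2pk(single$t, single$v, "ips")
  expect_true(is.na(pk3$pk1) && is.na(pk3$pk2))
})

test_that("per-cycle maximum extraction is the plain maximum", {
  expect_equal(extract_max(rep(80, 10)), 80)
  cyc <- make_cycle()
  pk <- extract_2pk(cyc$t, cyc$v, "fp")
  expect_equal(extract_max(cyc$v), max(pk$pk1, pk$pk2))
  expect_error(extract_max(numeric(0)), "no samples")
})

test_that("Bland-Altman statistics match hand arithmetic", {
  # identical pairs: no bias, no spread
  same <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$mod, 0)
  expect_equal(same$two_s, 0)

  # differences {-1, 0, +1}: MoD 0, SD 1, 2S 1.96
  ba <- bland_altman(c(9, 20, 31), c(10, 20, 30))
  expect_equal(ba$mod, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$two_s, 1.96)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)

  expect_error(bland_altman(1:2, 1:2), "at least 3")
  expect_error(bland_altman(1:3, 1:4), "paired")
})

test_that("Bland-Altman recovers a known difference distribution", {
  set.seed(7)
  n <- 10000
  fp <- runif(n, 60, 140)
  d <- rnorm(n, mean = 2, sd = 5)
  ba <- bland_altman(fp + d, fp)
  se_mod <- 5 / sqrt(n)
  expect_lt(abs(ba$mod - 2), 3 * se_mod)
  se_two_s <- 1.96 * 5 / sqrt(2 * (n - 1))
  expect_lt(abs(ba$two_s - 9.8), 3 * se_two_s)
  # two_s is exactly 1.96 sample SDs
  expect_identical(ba$two_s, 1.96 * ba$sd_diff)
  # with the error on one instrument only, regressing d on the pair mean
  # has a small structural slope var(d)/2 / var(mean); no extra trend
  slope_struct <- (5^2 / 2) / (80^2 / 12 + 5^2 / 4)
  expect_equal(ba$slope, slope_struct, tolerance = 0.3)
  expect_equal(ba$resid_sd, 5, tolerance = 0.05)
})

test_that("a fixed injected bias moves MoD and leaves 2S alone", {
  set.seed(8)
  fp <- runif(2000, 60, 140)
  ips <- fp + rnorm(2000, 0, 4)
  base <- bland_altman(ips, fp)
  shifted <- bland_altman(ips + 3, fp)
  expect_equal(shifted$mod, base$mod + 3, tolerance = 1e-12)
  expect_equal(shifted$two_s, base$two_s, tolerance = 1e-12)
})

test_that("stratified two-fold CV enumerates all eight splits", {
  trials <- as.list(1:6)
  speeds <- c(0.5, 0.5, 1.0, 1.0, 1.5, 1.5)
  seen <- list()
  fn <- function(cal, test) {
    seen[[length(seen) + 1]] <<- sort(unlist(cal))
    ba <- bland_altman(c(1, 2, 3), c(1, 2, 3) - unlist(cal)[1])
    list(max = ba)
  }
  cv <- stratified_two_fold_cv(trials, speeds, fn)
  expect_length(cv$iterations, 8)
  # all eight calibration folds are distinct
  expect_equal(length(unique(seen)), 8)
  # every fold holds one trial per speed
  for (fold in seen) {
    expect_equal(sort(speeds[fold]), c(0.5, 1.0, 1.5))
  }
  expect_error(stratified_two_fold_cv(trials[1:5], speeds[1:5], fn),
               "exactly 2 trials")

  # determinism: rerunning gives identical results
  cv2 <- stratified_two_fold_cv(trials, speeds, fn)
  expect_identical(cv$summary, cv2$summary)
})

test_that("the representative subset maximizes distribution overlap", {
  mk_cv <- function(mods, twos) {
    its <- lapply(seq_along(mods), function(i) {
      list(max = structure(list(mod = mods[i], two_s = twos[i]),
                           class = "bland_altman"))
    })
    structure(list(iterations = its), class = "cv_result")
  }
  # all identical: ties break to iteration 1
  expect_equal(select_representative_subset(mk_cv(rep(2, 8), rep(10, 8))), 1)
  # one iteration sits exactly on the mean, others displaced by 5
  mods <- c(2, 7, 7, 7, 7, -3, -3, 2)
  mods <- c(mean(mods), mods[-1])
  cv <- mk_cv(mods, rep(10, 8))
  expect_equal(select_representative_subset(cv), 1)
  # removing the winner changes which iteration is selected
  winner <- select_representative_subset(cv)
  remaining <- seq_along(mods)[-winner]
  cv2 <- mk_cv(mods[remaining], rep(10, 7))
  new_winner <- remaining[select_representative_subset(cv2)]
  expect_false(new_winner == winner)
})

test_that("normal overlap coefficient behaves like one", {
  expect_equal(normal_overlap(0, 1, 0, 1), 1, tolerance = 1e-8)
  # monotone decreasing in displacement
  o <- sapply(c(0, 1, 2, 4), function(d) normal_overlap(0, 1, d, 1))
  expect_true(all(diff(o) < 0))
  # closed form for equal SDs: 2 * pnorm(-|d|/(2s))
  expect_equal(normal_overlap(0, 2, 3, 2), 2 * pnorm(-3 / 4),
               tolerance = 1e-7)
  # unequal SDs: agrees with brute-force integration of min(f, g)
  brute <- function(m1, s1, m2, s2) {
    integrate(function(x) pmin(dnorm(x, m1, s1), dnorm(x, m2, s2)),
              min(m1 - 8 * s1, m2 - 8 * s2),
              max(m1 + 8 * s1, m2 + 8 * s2), rel.tol = 1e-10)$value
  }
  for (par in list(c(0, 1, 1, 3), c(2, 0.5, -1, 2), c(0, 1, 0, 5))) {
    expect_equal(normal_overlap(par[1], par[2], par[3], par[4]),
                 brute(par[1], par[2], par[3], par[4]), tolerance = 1e-6)
  }
  # robust for nearly-degenerate spreads
  expect_gt(normal_overlap(0, 1e-9, 0.5, 1), 0)
  expect_lt(normal_overlap(0, 1e-9, 0.5, 1), 0.7)
  expect_equal(normal_overlap(1, 0, 1, 0), 1)
  expect_equal(normal_overlap(1, 0, 2, 0), 0)
})
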