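#' Extract weight-acceptance and push-off peaks from one gait cycle
#'
#' Instrument-specific rules are used. Force plate: the maximum over the
#' first 30% of the cycle (approximately midstance) is the weight
#' acceptance peak, the maximum after 30% is the push-off peak. Insole:
#' the two largest local maxima whose width at half prominence exceeds
#' `min_width` seconds, returned in time order; narrow spikes are noise
#' artifacts and excluded. An insole cycle with fewer than two qualifying
#' peaks yields `NA`s (the cycle is excluded from the two-peak assessment
#' but still contributes to the per-cycle maximum).
#'
#' @param t,v Numeric vectors: times and force values of one cycle (any
#'   consistent force unit).
#' @param instrument `"fp"` or `"ips"`.
#' @param split_pct Force-plate cycle split in percent (default 30).
#' @param min_width Insole minimum peak width in seconds.
#' @return Named list `pk1`, `pk2`, `t1`, `t2` (values and times; `NA` if
#'   the insole rule finds fewer than two peaks).
#' @export
extract_2pk <- function(t, v, instrument = c("fp", "ips"),
                        split_pct = 30, min_width = 0.05) {
  instrument <- match.arg(instrument)
  if (length(t) < 3L) {
    return(list(pk1 = NA_real_, pk2 = NA_real_,
                t1 = NA_real_, t2 = NA_real_))
  }
  if (instrument == "fp") {
    pct <- 100 * (t - t[1L]) / (t[length(t)] - t[1L])
    first <- pct < split_pct
    i1 <- which.max(ifelse(first, v, -Inf))
    i2 <- which.max(ifelse(first, -Inf, v))
    list(pk1 = v[i1], pk2 = v[i2], t1 = t[i1], t2 = t[i2])
  } else {
    dt <- stats::median(diff(t))
    pk <- find_peaks(v, min_prominence = 1e-9)
    if (nrow(pk)) {
      w <- vapply(seq_len(nrow(pk)), function(j) {
        peak_width(v, pk$index[j], pk$prominence[j]) * dt
      }, numeric(1))
      pk <- pk[w > min_width, , drop = FALSE]
    }
    if (nrow(pk) < 2L) {
      return(list(pk1 = NA_real_, pk2 = NA_real_,
                  t1 = NA_real_, t2 = NA_real_))
    }
    top <- pk[order(pk$height, decreasing = TRUE)[1:2], ]
    top <- top[order(top$index), ]
    list(pk1 = top$height[1L], pk2 = top$height[2L],
         t1 = t[top$index[1L]], t2 = t[top$index[2L]])
  }
}

#' Per-cycle absolute maximum force
#'
#' @param v Non-empty numeric vector of force samples within one cycle.
#' @return The maximum sample value.
#' @export
extract_max <- function(v) {
  if (!length(v)) stop("cycle contains no samples", call. = FALSE)
  max(v)
}

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between paired insole and force-plate
#' measurements through the differences `d = ips - fp`: their mean (MoD,
#' the bias), the sample standard deviation, `2S = 1.96 SD` (the
#' half-width from the bias to each limit of agreement), the limits of
#' agreement themselves, a two-sided one-sample t-test of MoD against
#' zero, and a least-squares regression of the differences on the pair
#' means quantifying how bias varies with force magnitude.
#'
#' @param ips,fp Paired numeric vectors (same unit, typically %BW), >= 3
#'   pairs; `NA` pairs are dropped.
#' @return An object of class `bland_altman`: list with `mod`, `sd_diff`,
#'   `two_s`, `loa_low`, `loa_high`, `p_value`, `n_pairs`, `slope`,
#'   `intercept`, `resid_sd`.
#' @export
bland_altman <- function(ips, fp) {
  if (length(ips) != length(fp)) {
    stop("ips and fp must be paired", call. = FALSE)
  }
  ok <- is.finite(ips) & is.finite(fp)
  ips <- ips[ok]; fp <- fp[ok]
  if (length(ips) < 3L) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  d <- ips - fp
  m <- (ips + fp) / 2
  mod <- mean(d)
  sd_diff <- stats::sd(d)
  two_s <- 1.96 * sd_diff
  p <- if (sd_diff == 0) {
    if (mod == 0) 1 else 0
  } else {
    stats::t.test(d, mu = 0)$p.value
  }
  if (stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    resid_sd <- sqrt(sum(stats::resid(fit)^2) /
                       max(1L, stats::df.residual(fit)))
  } else {
    slope <- 0; intercept <- mod; resid_sd <- sd_diff
  }
  structure(
    list(mod = mod, sd_diff = sd_diff, two_s = two_s,
         loa_low = mod - two_s, loa_high = mod + two_s,
         p_value = p, n_pairs = length(d),
         slope = slope, intercept = intercept, resid_sd = resid_sd),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d: MoD = %.2f, 2S = %.2f (LoA %.2f .. %.2f), p = %.3g\n",
    x$n_pairs, x$mod, x$two_s, x$loa_low, x$loa_high, x$p_value))
  cat(sprintf("  bias vs magnitude: d = %.3f m %+0.3f, resid SD %.3f\n",
              x$slope, x$intercept, x$resid_sd))
  invisible(x)
}

#' Stratified two-fold cross-validation over walking trials
#'
#' Six trials per subject (two repetitions at each of three speeds) are
#' split into a calibration fold and a test fold such that each fold
#' holds exactly one trial per speed. All `2^3 = 8` such assignments are
#' enumerated; for each, `analysis_fn(cal_trials, test_trials)` refits
#' the total-force calibration on the calibration fold and evaluates the
#' agreement analyses on the test fold.
#'
#' @param trials List of trial objects.
#' @param speeds Numeric vector labelling each trial's speed; exactly two
#'   trials per distinct speed required.
#' @param analysis_fn Function of (calibration trials, test trials)
#'   returning a named list of `bland_altman` results (e.g. `max` and
#'   `twopk`).
#' @return An object of class `cv_result`: list with `iterations` (list
#'   of per-iteration analysis results), `assignments` (matrix of
#'   which repetition went into the calibration fold per speed), and
#'   `summary` (data frame of per-assessment mean and SD of MoD and 2S
#'   across iterations).
#' @export
stratified_two_fold_cv <- function(trials, speeds, analysis_fn) {
  if (length(trials) != length(speeds)) {
    stop("speeds must label each trial", call. = FALSE)
  }
  sp <- sort(unique(speeds))
  by_speed <- lapply(sp, function(s) which(speeds == s))
  if (any(lengths(by_speed) != 2L)) {
    stop("need exactly 2 trials at each speed; got ",
         paste(lengths(by_speed), collapse = ", "), call. = FALSE)
  }
  picks <- as.matrix(expand.grid(rep(list(1:2), length(sp))))
  colnames(picks) <- paste0("speed_", sp)
  iterations <- vector("list", nrow(picks))
  for (i in seq_len(nrow(picks))) {
    cal_idx <- vapply(seq_along(sp), function(j) by_speed[[j]][picks[i, j]],
                      integer(1))
    test_idx <- setdiff(unlist(by_speed), cal_idx)
    iterations[[i]] <- analysis_fn(trials[cal_idx], trials[test_idx])
  }
  assessments <- names(Filter(function(x) inherits(x, "bland_altman"),
                              iterations[[1L]]))
  summ <- do.call(rbind, lapply(assessments, function(a) {
    mods <- vapply(iterations, function(it) it[[a]]$mod, numeric(1))
    twos <- vapply(iterations, function(it) it[[a]]$two_s, numeric(1))
    data.frame(assessment = a,
               mod_mean = mean(mods), mod_sd = stats::sd(mods),
               two_s_mean = mean(twos), two_s_sd = stats::sd(twos))
  }))
  structure(list(iterations = iterations, assignments = picks,
                 summary = summ),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d iterations\n", length(x$iterations)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Overlap coefficient of two normal densities
#'
#' The overlapping area `integral of min(f, g)` of two normal densities,
#' in [0, 1]; 1 iff the distributions coincide. Computed in closed form
#' from the crossing points of the two densities (equal-SD pair: one
#' crossing at the midpoint; unequal SDs: the two roots of the log-density
#' difference), so it is exact and robust for nearly-degenerate inputs.
#' Zero-SD distributions overlap fully iff both are point masses at the
#' same location.
#'
#' @param m1,s1,m2,s2 Means and standard deviations.
#' @return Overlap coefficient in [0, 1].
#' @export
normal_overlap <- function(m1, s1, m2, s2) {
  if (s1 <= 0 || s2 <= 0) {
    return(as.numeric(s1 == s2 && m1 == m2))
  }
  if (abs(s1 - s2) < 1e-12 * max(s1, s2)) {
    return(2 * stats::pnorm(-abs(m1 - m2) / (s1 + s2)))
  }
  if (s1 > s2) {
    tmp <- m1; m1 <- m2; m2 <- tmp
    tmp <- s1; s1 <- s2; s2 <- tmp
  }
  # s1 < s2: the narrow density exceeds the wide one between the two
  # crossings of the log-density difference and is smaller outside
  A <- 1 / s2^2 - 1 / s1^2
  B <- 2 * (m1 / s1^2 - m2 / s2^2)
  C <- m2^2 / s2^2 - m1^2 / s1^2 + 2 * log(s2 / s1)
  disc <- sqrt(B^2 - 4 * A * C)
  x <- sort(c((-B - disc) / (2 * A), (-B + disc) / (2 * A)))
  stats::pnorm(x[1L], m1, s1) + 1 - stats::pnorm(x[2L], m1, s1) +
    stats::pnorm(x[2L], m2, s2) - stats::pnorm(x[1L], m2, s2)
}

#' Pick the cross-validation iteration most representative of the mean
#'
#' Each iteration's maximum-force assessment defines a normal
#' distribution `N(MoD_i, (2S_i / 1.96)^2)`; the representative iteration
#' maximizes the overlap coefficient with the mean distribution
#' `N(mean MoD, (mean 2S / 1.96)^2)`. Ties break to the lowest iteration
#' index.
#'
#' @param cv A `cv_result`.
#' @param assessment Name of the assessment used (default `"max"`).
#' @return Integer iteration index.
#' @export
select_representative_subset <- function(cv, assessment = "max") {
  mods <- vapply(cv$iterations, function(it) it[[assessment]]$mod,
                 numeric(1))
  twos <- vapply(cv$iterations, function(it) it[[assessment]]$two_s,
                 numeric(1))
  m_bar <- mean(mods)
  s_bar <- mean(twos) / 1.96
  ovl <- vapply(seq_along(mods), function(i) {
    normal_overlap(mods[i], twos[i] / 1.96, m_bar, s_bar)
  }, numeric(1))
  which.max(ovl)  # which.max breaks ties at the first index
}
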