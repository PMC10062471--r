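#' Extract loading phases from a step calibration trial
#'
#' Each calibration "step" loads the sensor from zero up to body weight;
#' only the loading limb of each step (initial contact up to the first
#' force peak) is used for calibration. Contact is the first sample with
#' force above `contact_frac` of body weight *and* resistance below 98% of
#' its unloaded baseline; the phase ends at the step's force peak
#' (prominence above `prominence_frac` of body weight). Force is
#' interpolated onto the insole timestamps so each phase yields paired
#' (resistance, force) samples.
#'
#' @param trial A `calibration_trial`.
#' @param contact_frac Contact threshold as a fraction of body weight.
#' @param prominence_frac Minimum peak prominence as a fraction of body
#'   weight.
#' @param baseline_frac Unloaded-resistance threshold fraction.
#' @return List of data frames, one per step, with columns `t`, `R`
#'   (ohm), `F` (N), ordered by time.
#' @export
extract_loading_phases <- function(trial, contact_frac = 0.02,
                                   prominence_frac = 0.20,
                                   baseline_frac = 0.98) {
  bw <- trial$subject$body_weight
  fp <- trial$fp_force
  r <- trial$ips_resistance
  f_at_ips <- stats::approx(fp$timestamps, fp$values,
                            xout = r$timestamps, rule = 2)$y
  pk <- find_peaks(fp$values, min_prominence = prominence_frac * bw)
  # a ramp still rising at the end of the record peaks at the final sample
  nfp <- length(fp$values)
  if (fp$values[nfp] > fp$values[nfp - 1L] &&
      fp$values[nfp] - min(fp$values) >= prominence_frac * bw) {
    pk <- rbind(pk, data.frame(index = nfp, height = fp$values[nfp],
                               prominence = fp$values[nfp] -
                                 min(fp$values)))
  }
  if (nrow(pk) < trial$n_steps) {
    stop(sprintf(
      "expected %d loading steps but found %d force peaks (at %s s)",
      trial$n_steps, nrow(pk),
      paste(round(fp$timestamps[pk$index], 2), collapse = ", ")),
      call. = FALSE)
  }
  pk <- pk[order(pk$height, decreasing = TRUE)[seq_len(trial$n_steps)], ]
  pk <- pk[order(pk$index), ]
  baseline <- max(r$values)
  out <- vector("list", trial$n_steps)
  prev_peak_t <- -Inf
  for (k in seq_len(trial$n_steps)) {
    t_peak <- fp$timestamps[pk$index[k]]
    sel <- which(r$timestamps > prev_peak_t & r$timestamps <= t_peak)
    loaded <- f_at_ips[sel] > contact_frac * bw &
      r$values[sel] < baseline_frac * baseline
    if (!any(loaded)) {
      stop("no loading samples found for step ", k, call. = FALSE)
    }
    # contact = start of the last contiguous loaded run before the peak
    # (the window may begin inside the previous step's unloading limb)
    runs <- rle(loaded)
    run_ends <- cumsum(runs$lengths)
    run_starts <- run_ends - runs$lengths + 1L
    last_run <- max(which(runs$values))
    first <- sel[run_starts[last_run]]
    last <- sel[length(sel)]
    out[[k]] <- data.frame(t = r$timestamps[first:last],
                           R = r$values[first:last],
                           F = f_at_ips[first:last])
    prev_peak_t <- t_peak
  }
  out
}

# local maxima with prominence, computed the standard way: for each peak,
# the drop to the highest of the two lowest intervening saddles toward a
# higher peak (or the record edge)
find_peaks <- function(v, min_prominence = 0, min_height = -Inf) {
  idx <- local_maxima(v)
  idx <- idx[v[idx] >= min_height]
  if (!length(idx)) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(idx, function(i) peak_prominence(v, i), numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = idx[keep], height = v[idx[keep]],
             prominence = prom[keep])
}

peak_prominence <- function(v, i) {
  h <- v[i]
  # walk left until a sample higher than v[i]; track the minimum
  left <- if (i > 1L) {
    seg <- v[(i - 1L):1L]
    stop_at <- which(seg > h)[1L]
    if (is.na(stop_at)) min(seg) else min(seg[seq_len(stop_at)])
  } else h
  right <- if (i < length(v)) {
    seg <- v[(i + 1L):length(v)]
    stop_at <- which(seg > h)[1L]
    if (is.na(stop_at)) min(seg) else min(seg[seq_len(stop_at)])
  } else h
  h - max(left, right)
}

# width of peak i at half prominence, in samples, by linear interpolation
peak_width <- function(v, i, prominence) {
  ref <- v[i] - prominence / 2
  n <- length(v)
  jl <- i
  while (jl > 1L && v[jl] > ref) jl <- jl - 1L
  xl <- if (v[jl] > ref) jl else
    jl + (ref - v[jl]) / (v[jl + 1L] - v[jl])
  jr <- i
  while (jr < n && v[jr] > ref) jr <- jr + 1L
  xr <- if (v[jr] > ref) jr else
    jr - (ref - v[jr]) / (v[jr - 1L] - v[jr])
  xr - xl
}

#' Resample a loading phase on a uniform resistance grid
#'
#' Calibration samples are taken at resistance values spaced exactly
#' `step` ohms apart across the phase's resistance span (descending from
#' the contact resistance), with force linearly interpolated at each grid
#' resistance. This weights the fit uniformly in resistance rather than in
#' time, compensating for the slow dwell near the ends of a ramp.
#'
#' @param R,F Paired numeric vectors (ohms, newtons) from one loading
#'   phase.
#' @param step Resistance grid spacing in ohms.
#' @return Data frame with columns `R`, `F` on the grid; at least 2 rows.
#'   If the span is smaller than one step, the segment endpoints are
#'   returned with a warning.
#' @export
uniform_resistance_downsample <- function(R, F, step = 150) {
  if (length(R) != length(F)) stop("R and F must be paired", call. = FALSE)
  span <- max(R) - min(R)
  if (span < step) {
    warning("resistance span (", round(span, 1),
            " ohm) smaller than one grid step; using segment endpoints")
    return(data.frame(R = c(R[1L], R[length(R)]),
                      F = c(F[1L], F[length(F)])))
  }
  n_grid <- floor(span / step) + 1L
  grid <- max(R) - step * (seq_len(n_grid) - 1L)
  o <- order(R)
  f_at <- stats::approx(R[o], F[o], xout = grid, ties = mean)$y
  data.frame(R = grid, F = f_at)
}

#' Fit the per-sensor quadratic calibration
#'
#' Least-squares fit of force on conductance `G = 1/R`:
#' `F = a0 + a1 G + a2 G^2`. Conductance, not resistance, is the natural
#' regressor because the sensor's conductance grows monotonically with
#' load.
#'
#' @param pairs Data frame with columns `R` (ohm) and `F` (N), pooled over
#'   all loading phases.
#' @param subject_id Optional subject id stored for later guard checks.
#' @return An object of class `sensor_calibration`: coefficients `a0`,
#'   `a1`, `a2`, fit `r2`, and the fitted resistance range
#'   `r_min`/`r_max`.
#' @export
fit_sensor_polynomial <- function(pairs, subject_id = NULL) {
  if (any(pairs$R <= 0)) stop("resistance must be positive", call. = FALSE)
  g <- 1 / pairs$R
  if (length(unique(signif(g, 12))) < 3L) {
    stop("need at least 3 distinct conductance values to fit a quadratic",
         call. = FALSE)
  }
  fit <- stats::lm(F ~ g + I(g^2), data = data.frame(F = pairs$F, g = g))
  co <- unname(stats::coef(fit))
  sst <- sum((pairs$F - mean(pairs$F))^2)
  r2 <- if (sst == 0) {
    warning("response has zero variance; r2 undefined")
    NaN
  } else {
    1 - sum(stats::resid(fit)^2) / sst
  }
  cal <- structure(
    list(a0 = co[1L], a1 = co[2L], a2 = co[3L], r2 = r2,
         r_min = min(pairs$R), r_max = max(pairs$R),
         subject_id = subject_id),
    class = "sensor_calibration"
  )
  gg <- seq(1 / cal$r_max, 1 / cal$r_min, length.out = 64L)
  if (any(diff(cal$a0 + cal$a1 * gg + cal$a2 * gg^2) < 0)) {
    warning("fitted calibration is not monotone over the fitted range")
  }
  cal
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat(sprintf(
    "<sensor_calibration> F = %.4g + %.4g G + %.4g G^2 (G = 1/R), r2 = %.4f\n",
    x$a0, x$a1, x$a2, x$r2))
  cat(sprintf("  fitted over R in [%.0f, %.0f] ohm\n", x$r_min, x$r_max))
  invisible(x)
}

#' Convert a resistance record to force with a fitted calibration
#'
#' Applies `F = a0 + a1/R + a2/R^2`. Samples whose resistance falls below
#' the fitted range are extrapolations (forces above the calibrated
#' maximum, typically body weight) and are flagged in the
#' `"extrapolated"` attribute rather than rejected.
#'
#' @param resistance Resistance `sampled_signal` (ohm, values > 0).
#' @param cal A `sensor_calibration`.
#' @return Force `sampled_signal` in N with logical attribute
#'   `"extrapolated"`.
#' @export
apply_sensor_calibration <- function(resistance, cal) {
  if (any(resistance$values <= 0)) {
    stop("resistance must be positive", call. = FALSE)
  }
  if (!is.null(cal$subject_id) && !is.null(resistance$subject_id) &&
      !identical(cal$subject_id, resistance$subject_id)) {
    stop("calibration was fitted for subject '", cal$subject_id,
         "' but the signal belongs to subject '", resistance$subject_id,
         "'", call. = FALSE)
  }
  g <- 1 / resistance$values
  f <- cal$a0 + cal$a1 * g + cal$a2 * g^2
  out <- sampled_signal(resistance$timestamps, f, "N",
                        nominal_rate = resistance$nominal_rate,
                        subject_id = resistance$subject_id)
  attr(out, "extrapolated") <- resistance$values < cal$r_min |
    resistance$values > cal$r_max
  out
}

#' Fit a calibration trial end to end
#'
#' Convenience wrapper: extract loading phases, grid each on the uniform
#' resistance lattice, pool, and fit the quadratic.
#'
#' @param trial A `calibration_trial`.
#' @param step Resistance grid spacing in ohms.
#' @param ... Passed to [extract_loading_phases()].
#' @return A `sensor_calibration`.
#' @export
calibrate_sensor <- function(trial, step = 150, ...) {
  phases <- extract_loading_phases(trial, ...)
  pooled <- do.call(rbind, lapply(phases, function(ph) {
    uniform_resistance_downsample(ph$R, ph$F, step = step)
  }))
  fit_sensor_polynomial(pooled, subject_id = trial$subject$subject_id)
}

#' Fit the two-coefficient total-force calibration
#'
#' With only hindfoot and forefoot sensors, midfoot force goes unsensed;
#' total force is approximated as a scaled sum
#' `F_total = C_hind * F_hind + C_fore * F_fore` with no intercept (zero
#' sensor force must map to zero total force). Coefficients are fitted by
#' least squares on rows pairing the force-plate force at each gait-cycle
#' peak with the two sensor forces at the corresponding times.
#'
#' @param peak_rows Data frame with columns `F_fp`, `F_hind`, `F_fore`
#'   (consistent units), one row per cycle peak, >= 2 rows.
#' @param subject_id Optional id stored for guard checks.
#' @return An object of class `total_force_calibration` with `c_hind`,
#'   `c_fore`, `r2`, `n_rows`.
#' @export
fit_total_force <- function(peak_rows, subject_id = NULL) {
  if (nrow(peak_rows) < 2L) {
    stop("need at least 2 peak rows to fit the total-force scaling",
         call. = FALSE)
  }
  X <- cbind(peak_rows$F_hind, peak_rows$F_fore)
  if (qr(X)$rank < 2L) {
    stop("hindfoot and forefoot peak forces are collinear; ",
         "collect more cycles", call. = FALSE)
  }
  fit <- stats::lm.fit(X, peak_rows$F_fp)
  co <- unname(fit$coefficients)
  sst <- sum(peak_rows$F_fp^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else NaN
  if (any(co < 0.5 | co > 3.0)) {
    warning("total-force coefficients (", round(co[1L], 2), ", ",
            round(co[2L], 2), ") fall outside the plausible range ",
            "[0.5, 3.0]")
  }
  structure(
    list(c_hind = co[1L], c_fore = co[2L], r2 = r2,
         n_rows = nrow(peak_rows), subject_id = subject_id),
    class = "total_force_calibration"
  )
}

#' @export
print.total_force_calibration <- function(x, ...) {
  cat(sprintf(
    "<total_force_calibration> F_total = %.3f F_hind + %.3f F_fore (n = %d)\n",
    x$c_hind, x$c_fore, x$n_rows))
  invisible(x)
}

#' Total insole force from regional sensor forces
#'
#' @param f_hind,f_fore Aligned force `sampled_signal`s.
#' @param cal A `total_force_calibration`.
#' @return `C_hind * F_hind + C_fore * F_fore` on the shared grid.
#' @export
total_force <- function(f_hind, f_fore, cal) {
  stopifnot_same_grid(f_hind, f_fore)
  stopifnot_same_unit(f_hind, f_fore)
  with_values(f_hind, cal$c_hind * f_hind$values +
                cal$c_fore * f_fore$values)
}

#' Estimated midfoot force implied by the total-force calibration
#'
#' The scaled sum exceeds the raw sensor sum exactly by the force
#' attributed to the unsensed midfoot:
#' `F_mid = (C_hind - 1) F_hind + (C_fore - 1) F_fore`.
#'
#' @inheritParams total_force
#' @return Midfoot force `sampled_signal`.
#' @export
estimate_midfoot <- function(f_hind, f_fore, cal) {
  stopifnot_same_grid(f_hind, f_fore)
  stopifnot_same_unit(f_hind, f_fore)
  with_values(f_hind, (cal$c_hind - 1) * f_hind$values +
                (cal$c_fore - 1) * f_fore$values)
}
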