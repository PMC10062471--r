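#' Recover the insole-vs-force-plate clock offset from the stomp
#'
#' Each trial begins with a deliberate stomp that registers in both
#' instruments. The force-plate stomp onset is the first upward crossing
#' of 1.5 times the median walking peak; the insole stomp onset is the
#' (sub-sample, parabolically interpolated) steepest resistance drop
#' within the first `window` seconds of the record. The returned offset is
#' the amount to *subtract* from the insole timestamps to bring them onto
#' the force-plate clock.
#'
#' @param ips Resistance `sampled_signal` (ohm) on the insole clock.
#' @param fp Resultant-force `sampled_signal` (N) on the force-plate clock.
#' @param window Length (s) of the initial insole span searched for the
#'   stomp.
#' @return Estimated clock offset in seconds (ips time minus fp time).
#' @export
synchronize_stomp <- function(ips, fp, window = 5) {
  t_fp <- fp_stomp_onset(fp)
  if (is.na(t_fp)) {
    stop("no stomp transient found in the force-plate record; ",
         "supply the clock offset manually", call. = FALSE)
  }
  t_ips <- ips_stomp_onset(ips, window)
  if (is.na(t_ips)) {
    stop("no stomp transient found in the insole record; ",
         "supply the clock offset manually", call. = FALSE)
  }
  # map the FP threshold-crossing fiducial onto the max-slope fiducial:
  # the FP max-slope time in the same transient is the better analogue of
  # the insole steepest-drop time
  t_fp_slope <- fp_maxslope_near(fp, t_fp)
  t_ips - t_fp_slope
}

fp_stomp_onset <- function(fp) {
  v <- fp$values
  pk <- local_maxima(v)
  pk <- pk[v[pk] > 20]
  if (!length(pk)) return(NA_real_)
  thresh <- 1.5 * stats::median(v[pk])
  above <- v > thresh
  if (!any(above)) return(NA_real_)
  fp$timestamps[which(above)[1L]]
}

# time of maximum force slope within 0.3 s before the threshold crossing
fp_maxslope_near <- function(fp, t_cross) {
  sel <- which(fp$timestamps >= t_cross - 0.3 & fp$timestamps <= t_cross)
  if (length(sel) < 3L) return(t_cross)
  dv <- diff(fp$values[sel])
  i <- which.max(dv)
  (fp$timestamps[sel[i]] + fp$timestamps[sel[i + 1L]]) / 2
}

# steepest resistance drop in the first `window` seconds, refined by
# parabolic interpolation of the slope sequence; the drop is measured on
# the conductance (1/R) scale, which is locally proportional to force, so
# the fiducial lands at the transient's maximum force slope rather than at
# the low-force knee where dR/dF is largest
ips_stomp_onset <- function(ips, window = 5) {
  sel <- which(ips$timestamps <= ips$timestamps[1L] + window)
  if (length(sel) < 3L) return(NA_real_)
  tt <- ips$timestamps[sel]
  vv <- -1 / pmax(ips$values[sel], .Machine$double.eps)
  slope <- diff(vv) / diff(tt)
  tm <- (tt[-1L] + tt[-length(tt)]) / 2
  if (min(slope) >= 0) return(NA_real_)
  i <- which.min(slope)
  if (i == 1L || i == length(slope)) return(tm[i])
  # parabola through the three steepest-slope points
  y <- slope[(i - 1L):(i + 1L)]
  x <- tm[(i - 1L):(i + 1L)]
  denom <- (y[1L] - 2 * y[2L] + y[3L])
  if (abs(denom) < .Machine$double.eps) return(tm[i])
  tm[i] + 0.5 * (y[1L] - y[3L]) / denom * mean(diff(x))
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
}

#' Detect force-plate heel strikes
#'
#' A heel strike is the first sample at which the resultant force exceeds
#' `threshold` (20 N), provided the force stayed below the threshold for at
#' least `debounce` seconds beforehand (so noisy re-crossings within one
#' contact are not double-counted).
#'
#' @param force Uniform resultant-force `sampled_signal` in N.
#' @param threshold Force threshold in N.
#' @param debounce Minimum sub-threshold span (s) required before an
#'   event.
#' @return Numeric vector of heel-strike times (possibly empty).
#' @export
detect_hs_fp <- function(force, threshold = 20, debounce = 0.1) {
  stopifnot_uniform(force, "detect_hs_fp")
  if (force$unit != "N") stop("detect_hs_fp expects force in N",
                              call. = FALSE)
  above <- force$values > threshold
  n_db <- max(1L, round(debounce * force$nominal_rate))
  idx <- which(diff(c(FALSE, above)) == 1L)
  keep <- vapply(idx, function(i) {
    lo <- max(1L, i - n_db)
    i - lo >= n_db && !any(above[lo:(i - 1L)])
  }, logical(1))
  force$timestamps[idx[keep]]
}

#' Detect insole heel strikes from resistance
#'
#' An insole heel strike begins a span in which resistance stays below
#' `frac` (98%) of the baseline resistance for at least `min_duration`
#' (0.25 s); shorter dips are ignored. The event time is the first sample
#' of the qualifying span.
#'
#' @param resistance Resistance `sampled_signal` in ohms.
#' @param baseline Baseline (unloaded) resistance in ohms (> 0).
#' @param frac Threshold fraction of baseline.
#' @param min_duration Minimum sub-threshold dwell time in seconds.
#' @return Numeric vector of heel-strike times (possibly empty).
#' @export
detect_hs_ips <- function(resistance, baseline, frac = 0.98,
                          min_duration = 0.25) {
  if (!is.numeric(baseline) || length(baseline) != 1L || baseline <= 0) {
    stop("baseline must be a positive scalar resistance", call. = FALSE)
  }
  below <- resistance$values < frac * baseline
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- numeric(0)
  for (j in which(r$values)) {
    t0 <- resistance$timestamps[starts[j]]
    t1 <- resistance$timestamps[ends[j]]
    if (t1 - t0 >= min_duration) out <- c(out, t0)
  }
  out
}

#' Segment gait cycles from heel-strike events
#'
#' `k` heel strikes delimit `k - 1` contiguous half-open cycles
#' `[HS_i, HS_{i+1})`; within a cycle, percent-of-cycle is the linear map
#' sending the start to 0 and the next heel strike to 100.
#'
#' @param hs_times Sorted numeric vector of >= 2 heel-strike times.
#' @return An object of class `gait_cycles`: data frame with columns
#'   `cycle`, `start`, `end`.
#' @export
segment_cycles <- function(hs_times) {
  if (length(hs_times) < 2L) {
    stop("need at least 2 heel strikes to segment cycles", call. = FALSE)
  }
  if (is.unsorted(hs_times, strictly = TRUE)) {
    stop("hs_times must be strictly increasing", call. = FALSE)
  }
  k <- length(hs_times)
  structure(
    data.frame(cycle = seq_len(k - 1L),
               start = hs_times[-k], end = hs_times[-1L]),
    class = c("gait_cycles", "data.frame")
  )
}

#' Percent of gait cycle at given times
#'
#' @param cycles A `gait_cycles` object.
#' @param t Numeric vector of times.
#' @return Numeric vector in [0, 100); `NA` outside every cycle.
#' @export
percent_of_cycle <- function(cycles, t) {
  out <- rep(NA_real_, length(t))
  for (i in seq_len(nrow(cycles))) {
    sel <- t >= cycles$start[i] & t < cycles$end[i]
    out[sel] <- 100 * (t[sel] - cycles$start[i]) /
      (cycles$end[i] - cycles$start[i])
  }
  out
}
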