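#' Zero-phase Butterworth low-pass filter
#'
#' Force-plate records are low-pass filtered at 20 Hz with a fourth-order
#' Butterworth filter. By default the filter is applied forward-backward
#' (zero phase) so that event and peak timings are not lagged; note that
#' this squares the magnitude response relative to a single pass, so the
#' -3 dB point moves slightly below the nominal cutoff. Use
#' `phase = "single"` for a causal single pass.
#'
#' @param sig Uniformly sampled `sampled_signal`.
#' @param cutoff_hz Cutoff frequency in Hz (must be below Nyquist).
#' @param order Filter order.
#' @param phase `"zero"` (default, forward-backward) or `"single"`.
#' @return Filtered signal on the same grid.
#' @export
butterworth_lowpass <- function(sig, cutoff_hz = 20, order = 4,
                                phase = c("zero", "single")) {
  phase <- match.arg(phase)
  stopifnot_uniform(sig, "butterworth_lowpass")
  fs <- sig$nominal_rate
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff_hz must lie in (0, Nyquist)", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  y <- if (phase == "zero") {
    signal::filtfilt(bf, sig$values)
  } else {
    as.numeric(signal::filter(bf, sig$values))
  }
  with_values(sig, y)
}

#' Resample a (possibly irregular) signal onto a uniform grid
#'
#' Raw insole resistance is logged at a nominal 28 Hz with jittered
#' timestamps; for one-to-one comparison with the force plate it is
#' interpolated onto a uniform 2,000 Hz grid. Interpolation is by natural
#' cubic spline, which for band-limited content well below the source
#' Nyquist (walking GRF lives below ~10 Hz) reconstructs the waveform to
#' well under 1% RMS of amplitude. When the target rate is *below* the
#' source rate an FIR anti-aliasing low-pass (Hamming-windowed, cutoff at
#' 90% of the target Nyquist) is applied after gridding.
#'
#' @param sig `sampled_signal` with at least two samples.
#' @param target_hz Target sampling rate in Hz.
#' @return Uniform signal spanning the input's time range; the grid runs
#'   from the first input timestamp in steps of `1/target_hz`, giving
#'   `round(duration * target_hz) + 1` samples.
#' @export
resample_uniform <- function(sig, target_hz = 2000) {
  if (length(sig) < 2L) {
    stop("resample_uniform needs at least 2 samples", call. = FALSE)
  }
  if (target_hz <= 0) stop("target_hz must be positive", call. = FALSE)
  t0 <- sig$timestamps[1L]
  duration <- sig$timestamps[length(sig)] - t0
  n_out <- round(duration * target_hz) + 1L
  grid <- t0 + (seq_len(n_out) - 1L) / target_hz
  grid[n_out] <- min(grid[n_out], sig$timestamps[length(sig)])
  y <- stats::spline(sig$timestamps, sig$values, xout = grid,
                     method = "fmm")$y
  src_rate <- (length(sig) - 1L) / duration
  if (target_hz < src_rate) {
    # downsampling: remove content above the new Nyquist before use
    ntaps <- max(31L, 2L * ceiling(src_rate / target_hz) * 10L + 1L)
    ntaps <- min(ntaps, length(y) - 1L)
    if (ntaps %% 2L == 0L) ntaps <- ntaps - 1L
    h <- signal::fir1(ntaps - 1L, 0.9 * (target_hz / 2) / (src_rate / 2))
    y <- signal::filtfilt(h, 1, y)
  }
  sampled_signal(grid, y, sig$unit, nominal_rate = target_hz,
                 subject_id = sig$subject_id)
}

#' Binomial smoothing filter
#'
#' Smooths a uniformly sampled signal by `n_convolutions` successive
#' convolutions with the kernel (1, 2, 1)/4, i.e. by a single convolution
#' with the binomial kernel `choose(2n, k) / 4^n`, which for large `n`
#' closely approximates a Gaussian of variance `n/2` samples^2 (standard
#' deviation ~70.7 samples, 35 ms at 2,000 Hz, for the default
#' n = 10,000). The exact binomial kernel is used (computed stably via
#' `dbinom`) and applied by FFT convolution with edge-replication padding,
#' so DC gain is exactly 1.
#'
#' @param sig Uniformly sampled `sampled_signal`.
#' @param n_convolutions Number of elementary (1,2,1)/4 passes (>= 0).
#' @return Smoothed signal on the same grid.
#' @export
binomial_filter <- function(sig, n_convolutions = 10000) {
  stopifnot_uniform(sig, "binomial_filter")
  n <- n_convolutions
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("n_convolutions must be a non-negative integer", call. = FALSE)
  }
  if (n == 0) return(sig)
  kern <- binomial_kernel(n)
  half <- n
  x <- sig$values
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  y <- stats::convolve(xp, rev(kern), type = "filter")
  with_values(sig, y)
}

#' Binomial kernel of n elementary passes
#'
#' The impulse response of [binomial_filter()]: `dbinom(0:(2n), 2n, 1/2)`,
#' length `2n + 1`, unit sum, variance `n/2` samples^2.
#'
#' @param n_convolutions Number of (1,2,1)/4 passes.
#' @return Numeric kernel vector.
#' @export
binomial_kernel <- function(n_convolutions) {
  stats::dbinom(0:(2L * n_convolutions), 2L * n_convolutions, 0.5)
}

#' Detect unloaded spans of a resistance record
#'
#' A sensor is considered unloaded wherever its resistance lies within 2%
#' of the trial maximum (i.e. above `baseline_frac` times the maximum),
#' mirroring the 98%-of-baseline threshold used for insole heel-strike
#' detection.
#'
#' @param resistance `sampled_signal` in ohms.
#' @param baseline_frac Fraction of the trial maximum resistance above
#'   which the sensor counts as unloaded.
#' @return Logical vector, `TRUE` where unloaded.
#' @export
detect_unloaded <- function(resistance, baseline_frac = 0.98) {
  if (resistance$unit != "ohm") {
    stop("detect_unloaded expects a resistance signal", call. = FALSE)
  }
  resistance$values >= baseline_frac * max(resistance$values)
}

#' Subtract the unloaded baseline from a signal
#'
#' Sensor drift shifts the unloaded level of each trial, so trials are
#' zeroed by subtracting the mean of the signal over its unloaded
#' ("baseline") spans. Spans may be given explicitly as time windows, or
#' auto-detected from a reference resistance record (resistance within 2%
#' of the trial maximum); if neither is supplied the signal itself must be
#' a resistance record.
#'
#' @param sig `sampled_signal` to zero.
#' @param baseline_windows Optional 2-column matrix of (start, end) times.
#' @param reference Optional resistance `sampled_signal` on the same grid
#'   used to auto-detect unloaded spans.
#' @param baseline_frac Threshold fraction for auto-detection.
#' @return The zeroed signal, with the subtracted level in attribute
#'   `"baseline_value"`.
#' @export
zero_baseline <- function(sig, baseline_windows = NULL, reference = NULL,
                          baseline_frac = 0.98) {
  if (!is.null(baseline_windows)) {
    bw <- matrix(as.numeric(baseline_windows), ncol = 2L)
    mask <- rep(FALSE, length(sig))
    for (i in seq_len(nrow(bw))) {
      mask <- mask | (sig$timestamps >= bw[i, 1L] &
                      sig$timestamps <= bw[i, 2L])
    }
  } else {
    ref <- if (is.null(reference)) sig else {
      stopifnot_same_grid(sig, reference)
      reference
    }
    mask <- detect_unloaded(ref, baseline_frac)
  }
  if (!any(mask)) {
    stop("no unloaded baseline span found; supply baseline_windows",
         call. = FALSE)
  }
  b <- mean(sig$values[mask])
  out <- with_values(sig, sig$values - b)
  attr(out, "baseline_value") <- b
  out
}

#' Zero out force during swing
#'
#' Small calibrated-force residues remain during swing (sensor unloaded);
#' they are clamped to exactly zero wherever the unloaded mask is true.
#'
#' @param force Force `sampled_signal`.
#' @param unloaded_mask Logical vector aligned with `force`.
#' @return Force signal with unloaded samples set to 0.
#' @export
clamp_swing <- function(force, unloaded_mask) {
  if (length(unloaded_mask) != length(force)) {
    stop("unloaded_mask must align with the force signal", call. = FALSE)
  }
  v <- force$values
  v[unloaded_mask] <- 0
  with_values(force, v)
}
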