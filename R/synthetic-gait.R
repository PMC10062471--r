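#' Sensor response model
#'
#' A piezoresistive textile sensor is modelled with conductance affine-
#' quadratic in the applied force:
#' \deqn{R(F) = 1 / (1/R_0 + g_1 F + g_2 F^2)}
#' so resistance falls strictly monotonically from the unloaded baseline
#' `R0` as load increases. A linear additive drift on resistance and
#' additive Gaussian resistance noise complete the model. The quadratic
#' conductance term means the inverse map (force as a function of
#' conductance) is *close to* but not exactly a quadratic polynomial, so a
#' polynomial calibration fits well without being trivially exact.
#'
#' @param baseline_resistance Unloaded resistance R0 in ohms (> 0).
#' @param conductance_gain g1 in 1/(ohm N) (> 0).
#' @param conductance_curvature g2 in 1/(ohm N^2) (>= 0).
#' @param drift_rate Additive resistance drift in ohm/s.
#' @param noise_sd Additive resistance noise SD in ohms.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(baseline_resistance = 5000,
                         conductance_gain = 2e-6,
                         conductance_curvature = 1.5e-9,
                         drift_rate = 0.5,
                         noise_sd = 20) {
  stopifnot(baseline_resistance > 0, conductance_gain > 0,
            conductance_curvature >= 0, noise_sd >= 0)
  structure(
    list(baseline_resistance = baseline_resistance,
         conductance_gain = conductance_gain,
         conductance_curvature = conductance_curvature,
         drift_rate = drift_rate, noise_sd = noise_sd),
    class = "sensor_model"
  )
}

#' Synthetic subject description
#'
#' Ground-truth parameters for one simulated subject. Stance force is
#' partitioned between hindfoot, midfoot and forefoot regions; only the
#' hindfoot and forefoot carry sensors, and each sensor captures a
#' fraction (`true_coverage_*`) of its region's force. The constant
#' midfoot share `region_share_mid` is the force fraction no sensor sees,
#' which the two-coefficient total-force calibration must recover.
#'
#' @param subject_id Character id.
#' @param body_weight Body weight in newtons (default 737.7 N, i.e. a
#'   75.2 kg adult).
#' @param foot_area Plantar contact area in cm^2 (reporting metadata).
#' @param true_coverage_hind,true_coverage_fore Fraction in (0, 1] of each
#'   region's force seen by its sensor.
#' @param region_share_mid Fraction in [0, 1) of stance force routed
#'   through the unsensed midfoot.
#' @param hind_sensor,fore_sensor `sensor_model` objects.
#' @param rng_seed Integer seed associated with the subject.
#' @return An object of class `subject_model`.
#' @export
subject_model <- function(subject_id = "S01",
                          body_weight = 75.2 * 9.81,
                          foot_area = 40,
                          true_coverage_hind = 0.75,
                          true_coverage_fore = 0.85,
                          region_share_mid = 0.12,
                          hind_sensor = sensor_model(),
                          fore_sensor = sensor_model(
                            baseline_resistance = 5600,
                            conductance_gain = 1.7e-6,
                            conductance_curvature = 1.2e-9),
                          rng_seed = 1L) {
  stopifnot(body_weight > 0, foot_area > 0,
            true_coverage_hind > 0, true_coverage_hind <= 1,
            true_coverage_fore > 0, true_coverage_fore <= 1,
            region_share_mid >= 0, region_share_mid < 1)
  structure(
    list(subject_id = subject_id, body_weight = body_weight,
         foot_area = foot_area,
         true_coverage_hind = true_coverage_hind,
         true_coverage_fore = true_coverage_fore,
         region_share_mid = region_share_mid,
         hind_sensor = hind_sensor, fore_sensor = fore_sensor,
         rng_seed = as.integer(rng_seed)),
    class = "subject_model"
  )
}

# raised cosine lobe on |u - center| <= halfwidth, zero outside; zero value
# and zero slope at the support edges
raised_cosine <- function(u, center, halfwidth) {
  d <- abs(u - center)
  ifelse(d <= halfwidth, 0.5 * (1 + cos(pi * d / halfwidth)), 0)
}

# stance-normalized double-peaked GRF shape in %BW: two peak lobes placed so
# their supports exclude each other's centers, plus a midstance valley lobe
# whose support excludes both peak locations, so the configured peak heights
# are attained exactly
stance_shape <- function(u, peak1, peak2, valley) {
  peak1 * raised_cosine(u, 0.28, 0.28) +
    peak2 * raised_cosine(u, 0.72, 0.28) +
    valley * raised_cosine(u, 0.50, 0.18)
}

# stride period by treadmill speed: ~1.98 / 1.40 / 1.14 s at 0.5/1.0/1.5 m/s
stride_time <- function(speed) 1.4 / sqrt(speed)

#' Generate a double-peaked walking GRF waveform
#'
#' Builds a resultant ground-reaction-force time series at `fs` Hz made of
#' `n_cycles` gait cycles. Each stance phase (62% of the cycle) is an
#' "M"-shaped curve: weight-acceptance and push-off lobes with configured
#' peak heights (%BW) and a midstance valley; force is exactly zero during
#' swing. Per-cycle peak heights vary by a Gaussian perturbation of SD
#' `peak_sd` (%BW); set `peak_sd = 0` for a noise-free waveform whose
#' stance maxima equal the configured peaks exactly. Heel-strike truth
#' times are defined as the first sample of each cycle at which force
#' exceeds 20 N.
#'
#' @param speed Walking speed in m/s (> 0); sets the stride period.
#' @param n_cycles Number of gait cycles (>= 0).
#' @param subject `subject_model` (provides body weight).
#' @param seed Integer seed for the per-cycle peak variation.
#' @param peaks Length-2 numeric: nominal (weight-acceptance, push-off)
#'   peak heights in %BW.
#' @param valley Midstance valley lobe height in %BW.
#' @param peak_sd Per-cycle SD of each peak height in %BW.
#' @param fs Sampling rate in Hz.
#' @param t_start Time of the first heel contact (s).
#' @return A list with `grf` (a `sampled_signal` in N covering
#'   `t_start .. t_start + n_cycles * stride`), `hs_times` (truth
#'   heel-strike times, s), and `cycle_peaks` (matrix of realized per-cycle
#'   peak heights in %BW).
#' @export
generate_grf_waveform <- function(speed, n_cycles, subject, seed = 1L,
                                  peaks = c(110, 105), valley = 75,
                                  peak_sd = 0, fs = 2000, t_start = 0) {
  if (!is.numeric(speed) || speed <= 0) {
    stop("speed must be positive", call. = FALSE)
  }
  if (n_cycles < 0 || n_cycles != round(n_cycles)) {
    stop("n_cycles must be a non-negative integer", call. = FALSE)
  }
  period <- stride_time(speed)
  if (n_cycles == 0) {
    return(list(grf = sampled_signal(numeric(0), numeric(0), "N",
                                     nominal_rate = fs,
                                     subject_id = subject$subject_id),
                hs_times = numeric(0),
                cycle_peaks = matrix(numeric(0), ncol = 2,
                                     dimnames = list(NULL, c("pk1", "pk2")))))
  }
  cyc_peaks <- with_seed(seed, {
    cbind(pk1 = peaks[1] + stats::rnorm(n_cycles, 0, peak_sd),
          pk2 = peaks[2] + stats::rnorm(n_cycles, 0, peak_sd))
  })
  duration <- n_cycles * period
  n <- round(duration * fs) + 1L
  t <- t_start + (seq_len(n) - 1L) / fs
  phase <- (t - t_start) / period          # cycles since first contact
  idx <- pmin(floor(phase) + 1L, n_cycles) # cycle index per sample
  u <- (phase - (idx - 1L)) / 0.62         # stance-normalized position
  v <- ifelse(u <= 1,
              stance_shape(u, cyc_peaks[idx, 1L], cyc_peaks[idx, 2L], valley),
              0)
  v <- v * subject$body_weight / 100       # %BW -> N
  grf <- sampled_signal(t, v, "N", nominal_rate = fs,
                        subject_id = subject$subject_id)
  hs <- find_truth_hs(t, v, idx, n_cycles)
  list(grf = grf, hs_times = hs, cycle_peaks = cyc_peaks)
}

# first 20 N exceedance within each cycle
find_truth_hs <- function(t, v, idx, n_cycles) {
  vapply(seq_len(n_cycles), function(k) {
    sel <- which(idx == k & v > 20)
    if (length(sel)) t[sel[1L]] else NA_real_
  }, numeric(1))
}

#' Partition total GRF into hindfoot, midfoot and forefoot forces
#'
#' Stance phases are identified as contiguous runs of positive force; the
#' within-stance position `u` in [0, 1] drives a smooth hand-off from
#' hindfoot-dominant loading at early stance to forefoot-dominant loading
#' at late stance (raised-cosine cross-fade), while a constant fraction
#' `region_share_mid` of the force is routed through the unsensed midfoot.
#' The three outputs sum to the input exactly at every sample.
#'
#' @param grf Non-negative total-force `sampled_signal`.
#' @param subject `subject_model` providing `region_share_mid`.
#' @return A list of `sampled_signal`s `hind`, `mid`, `fore`.
#' @export
decompose_regional_forces <- function(grf, subject) {
  v <- grf$values
  if (any(v < 0)) stop("grf must be non-negative", call. = FALSE)
  m <- subject$region_share_mid
  u <- stance_position(v)
  a_h <- 0.5 * (1 + cos(pi * u))           # 1 at contact -> 0 at toe-off
  hind <- (1 - m) * a_h * v
  fore <- (1 - m) * (1 - a_h) * v
  mid <- v - hind - fore                   # == m * v, exact conservation
  list(hind = with_values(grf, hind),
       mid = with_values(grf, mid),
       fore = with_values(grf, fore))
}

# within-run position in [0, 1] for each sample of each positive-force run
stance_position <- function(v) {
  u <- rep(0.5, length(v))
  loaded <- v > 0
  r <- rle(loaded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    n <- r$lengths[j]
    u[starts[j]:ends[j]] <- if (n == 1L) 0.5 else
      (seq_len(n) - 1L) / (n - 1L)
  }
  u
}

#' Map force seen by a sensor to its resistance record
#'
#' Applies the monotone sensor law `R = 1/(1/R0 + g1 F + g2 F^2)`, then
#' adds linear drift (`drift_rate * t`) and, if `noise = TRUE`, additive
#' Gaussian resistance noise.
#'
#' @param force `sampled_signal` of the force actually seen by the sensor
#'   (regional force times coverage), in N, all values finite and >= 0.
#' @param sensor `sensor_model`.
#' @param seed Integer seed for the noise draw.
#' @param noise Logical; include resistance noise?
#' @return Resistance `sampled_signal` in ohms.
#' @export
force_to_resistance <- function(force, sensor, seed = 1L, noise = TRUE) {
  f <- force$values
  if (any(!is.finite(f))) stop("force must be finite", call. = FALSE)
  if (any(f < 0)) stop("force must be non-negative", call. = FALSE)
  g <- 1 / sensor$baseline_resistance +
    sensor$conductance_gain * f + sensor$conductance_curvature * f^2
  r <- 1 / g + sensor$drift_rate * (force$timestamps - force$timestamps[1L])
  if (noise && sensor$noise_sd > 0) {
    r <- r + with_seed(seed, stats::rnorm(length(r), 0, sensor$noise_sd))
  }
  sampled_signal(force$timestamps, r, "ohm",
                 nominal_rate = force$nominal_rate,
                 subject_id = force$subject_id)
}

#' Closed-form inverse of the sensor law
#'
#' Recovers the force seen by the sensor from drift- and noise-free
#' resistance: with conductance excess `q = 1/R - 1/R0`,
#' `F = (-g1 + sqrt(g1^2 + 4 g2 q)) / (2 g2)` (or `q/g1` when `g2 = 0`).
#'
#' @param resistance Resistance `sampled_signal` in ohms (> 0).
#' @param sensor `sensor_model`.
#' @return Force `sampled_signal` in N.
#' @export
resistance_to_force <- function(resistance, sensor) {
  r <- resistance$values
  if (any(r <= 0)) stop("resistance must be positive", call. = FALSE)
  q <- 1 / r - 1 / sensor$baseline_resistance
  g1 <- sensor$conductance_gain
  g2 <- sensor$conductance_curvature
  f <- if (g2 > 0) (-g1 + sqrt(g1^2 + 4 * g2 * pmax(q, -g1^2 / (4 * g2)))) /
    (2 * g2) else q / g1
  sampled_signal(resistance$timestamps, f, "N",
                 nominal_rate = resistance$nominal_rate,
                 subject_id = resistance$subject_id)
}

# jittered insole sampling clock: nominal rate with uniform +/-10% period
# jitter, reproducing the observed 28 +/- 1.2 Hz spread
ips_clock <- function(duration, seed, nominal_hz = 28, jitter = 0.10) {
  dt <- 1 / nominal_hz
  n <- ceiling(duration / dt) + 8L
  incr <- with_seed(seed, dt * (1 + stats::runif(n, -jitter, jitter)))
  t <- cumsum(c(0, incr))
  t[t <= duration]
}

#' Generate a single-sensor step calibration trial
#'
#' Emulates the calibration protocol: the subject slowly shifts full body
#' weight onto one sensor region and back off, three times. The force-plate
#' channel records the applied ramp at `fs` Hz; the insole channel records
#' the corresponding sensor resistance on a jittered ~28 Hz clock. The
#' sensor sees `true_coverage * F`, so the per-sensor calibration learns
#' coverage implicitly. Each noise-free ramp peaks exactly at body weight.
#'
#' @param subject `subject_model`.
#' @param region `"hind"` or `"fore"`.
#' @param seed Integer seed.
#' @param n_steps Number of loading-unloading ramps.
#' @param noise Logical; include sensor resistance noise?
#' @param fs Force-plate sampling rate (Hz).
#' @return An object of class `calibration_trial`: list with `fp_force`
#'   (N), `ips_resistance` (ohm, irregular), `region`, `subject`,
#'   `ramp_windows` (matrix of per-step (start, peak, end) times), and
#'   `n_steps`.
#' @export
generate_calibration_trial <- function(subject, region = c("hind", "fore"),
                                       seed = 1L, n_steps = 3,
                                       noise = TRUE, fs = 2000) {
  region <- match.arg(region)
  if (n_steps < 1 || n_steps != round(n_steps)) {
    stop("n_steps must be a positive integer", call. = FALSE)
  }
  sensor <- if (region == "hind") subject$hind_sensor else subject$fore_sensor
  coverage <- if (region == "hind") subject$true_coverage_hind else
    subject$true_coverage_fore
  ramp_dur <- 6; gap <- 2; lead <- 2
  duration <- lead + n_steps * (ramp_dur + gap)
  n <- round(duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  f <- numeric(n)
  ramps <- matrix(NA_real_, n_steps, 3,
                  dimnames = list(NULL, c("start", "peak", "end")))
  for (k in seq_len(n_steps)) {
    s <- lead + (k - 1) * (ramp_dur + gap)
    ramps[k, ] <- c(s, s + ramp_dur / 2, s + ramp_dur)
    f <- f + subject$body_weight *
      raised_cosine(t, s + ramp_dur / 2, ramp_dur / 2)
  }
  fp <- sampled_signal(t, f, "N", nominal_rate = fs,
                       subject_id = subject$subject_id)
  t_ips <- ips_clock(duration, seed = seed + 1000L)
  f_seen <- coverage * stats::approx(t, f, xout = t_ips, rule = 2)$y
  seen <- sampled_signal(t_ips, f_seen, "N",
                         subject_id = subject$subject_id)
  r <- force_to_resistance(seen, sensor, seed = seed + 2000L, noise = noise)
  structure(
    list(fp_force = fp, ips_resistance = r, region = region,
         subject = subject, ramp_windows = ramps, n_steps = n_steps),
    class = "calibration_trial"
  )
}

#' Generate a 30-s walking trial with ground truth
#'
#' Produces paired force-plate and insole records for one treadmill trial:
#' 60,000 force-plate samples (2,000 Hz x 30 s) and jittered ~28 Hz
#' resistance records for the hindfoot and forefoot sensors. The timeline
#' is: quiet standing-free lead-in, one 0.2-s stomp transient (amplitude
#' `stomp_peak` %BW, well above any walking peak, used to synchronize the
#' two instruments), a short pause, then continuous gait cycles until the
#' end of the trial. The insole timestamps are shifted by `clock_offset`
#' to emulate unsynchronized acquisition clocks. All ground truth (heel
#' strikes, per-cycle peaks, stomp time, offset) is retained.
#'
#' @param subject `subject_model`.
#' @param speed Walking speed in m/s; one of `speeds`.
#' @param seed Integer seed (drives peak variation, clock jitter, noise).
#' @param duration Trial length in seconds.
#' @param clock_offset Insole clock minus force-plate clock, in seconds.
#' @param noise Logical; sensor resistance noise on/off.
#' @param peak_sd Per-cycle peak-height SD in %BW (0 = identical cycles).
#' @param stomp_peak Stomp amplitude in %BW.
#' @param speeds Admissible speed set.
#' @param fs Force-plate rate (Hz).
#' @return An object of class `walking_trial`: list with `fp_force` (N,
#'   uniform), `ips_hind`, `ips_fore` (ohm, irregular, offset clock),
#'   `speed`, `duration`, `subject`, and a `truth` list (`hs_times`,
#'   `stomp_time`, `clock_offset`, `cycle_peaks`, regional signals'
#'   truth-free of noise is re-derivable from the subject model).
#' @export
generate_walking_trial <- function(subject, speed, seed = 1L, duration = 30,
                                   clock_offset = 0, noise = TRUE,
                                   peak_sd = 4, stomp_peak = 180,
                                   speeds = c(0.5, 1.0, 1.5), fs = 2000) {
  if (!speed %in% speeds) {
    stop("speed must be one of ", paste(speeds, collapse = ", "),
         call. = FALSE)
  }
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  period <- stride_time(speed)
  gait_start <- 4
  n_cycles <- floor((duration - gait_start - 0.5) / period)
  wav <- generate_grf_waveform(speed, n_cycles, subject, seed = seed,
                               peak_sd = peak_sd, fs = fs,
                               t_start = gait_start)
  f <- numeric(n)
  sel <- t >= gait_start & t <= max(wav$grf$timestamps)
  f[sel] <- stats::approx(wav$grf$timestamps, wav$grf$values,
                          xout = t[sel])$y
  # stomp: short high transient at t = 2 s, before gait begins
  stomp_center <- 2
  f <- f + stomp_peak / 100 * subject$body_weight *
    raised_cosine(t, stomp_center, 0.1)
  fp <- sampled_signal(t, f, "N", nominal_rate = fs,
                       subject_id = subject$subject_id)
  reg <- decompose_regional_forces(fp, subject)
  t_ips <- ips_clock(duration - 1 / 28, seed = seed + 3000L)
  mk_ips <- function(regional, coverage, sensor, sub_seed) {
    f_seen <- coverage * stats::approx(t, regional$values, xout = t_ips,
                                       rule = 2)$y
    seen <- sampled_signal(t_ips, f_seen, "N",
                           subject_id = subject$subject_id)
    r <- force_to_resistance(seen, sensor, seed = seed + sub_seed,
                             noise = noise)
    sampled_signal(t_ips + clock_offset, r$values, "ohm",
                   subject_id = subject$subject_id)
  }
  ips_hind <- mk_ips(reg$hind, subject$true_coverage_hind,
                     subject$hind_sensor, 4000L)
  ips_fore <- mk_ips(reg$fore, subject$true_coverage_fore,
                     subject$fore_sensor, 5000L)
  stomp_onset <- t[f > 20 & t > stomp_center - 0.2][1L]
  structure(
    list(fp_force = fp, ips_hind = ips_hind, ips_fore = ips_fore,
         speed = speed, duration = duration, subject = subject,
         truth = list(hs_times = wav$hs_times,
                      stomp_time = stomp_onset,
                      stomp_center = stomp_center,
                      clock_offset = clock_offset,
                      cycle_peaks = wav$cycle_peaks)),
    class = "walking_trial"
  )
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
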