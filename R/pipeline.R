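#' Pipeline configuration with standard defaults
#'
#' Collects every stage parameter in one place. Defaults are the
#' protocol's standard values: force plate at 2,000 Hz filtered at 20 Hz
#' with a 4th-order Butterworth; insole nominally 28 Hz, resampled to
#' 2,000 Hz and smoothed with a 10,000-pass binomial filter; unloaded
#' threshold at 98% of baseline resistance with a 0.25-s dwell for insole
#' heel strikes; 20 N force-plate heel-strike threshold; 30%-of-cycle
#' split and 0.05-s minimum insole peak width for peak extraction; 150-ohm
#' calibration grid; PWB simulation at 50 +/- 25 %BW against a 50 %BW
#' limit with 1e7 draws.
#'
#' @param ... Overrides for any default (unknown names are an error).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    fp_rate_hz = 2000, fp_cutoff_hz = 20, fp_order = 4,
    ips_nominal_hz = 28, ips_resample_hz = 2000, ips_binomial_n = 10000,
    baseline_frac = 0.98, ips_hs_min_duration = 0.25,
    hs_threshold_n = 20, hs_debounce_s = 0.1,
    peak_split_pct = 30, peak_min_width_s = 0.05,
    resistance_step_ohm = 150,
    pwb_mu = 50, pwb_sigma = 25, pwb_limit = 50, pwb_n = 1e7,
    speeds = c(0.5, 1.0, 1.5), reps = 2, duration_s = 30,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write a walking trial to plain-text files
#'
#' Force-plate samples go to `<prefix>_fp.csv` (`t_s,fx_N,fy_N,fz_N`; the
#' resultant is stored in `fz_N` with zero shear columns), insole samples
#' to `<prefix>_ips.csv` (`t_s,r_hind_ohm,r_fore_ohm`; the two sensors'
#' jittered clocks are merged onto the hindfoot timestamps), and subject
#' metadata to `<prefix>_subject.json`.
#'
#' @param trial A `walking_trial`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_trial <- function(trial, prefix) {
  fp_path <- paste0(prefix, "_fp.csv")
  ips_path <- paste0(prefix, "_ips.csv")
  subj_path <- paste0(prefix, "_subject.json")
  utils::write.csv(
    data.frame(t_s = trial$fp_force$timestamps, fx_N = 0, fy_N = 0,
               fz_N = trial$fp_force$values),
    fp_path, row.names = FALSE)
  r_fore <- stats::approx(trial$ips_fore$timestamps, trial$ips_fore$values,
                          xout = trial$ips_hind$timestamps, rule = 2)$y
  utils::write.csv(
    data.frame(t_s = trial$ips_hind$timestamps,
               r_hind_ohm = trial$ips_hind$values,
               r_fore_ohm = r_fore),
    ips_path, row.names = FALSE)
  write_subject(trial$subject, subj_path)
  invisible(c(fp = fp_path, ips = ips_path, subject = subj_path))
}

#' Write subject metadata as JSON
#'
#' @param subject A `subject_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_subject <- function(subject, path) {
  jsonlite::write_json(
    list(subject_id = subject$subject_id,
         body_weight_N = subject$body_weight,
         foot_area_cm2 = subject$foot_area),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read subject metadata from JSON
#'
#' @param path JSON path with fields `subject_id`, `body_weight_N`,
#'   `foot_area_cm2`.
#' @return A `subject_model` (sensor/coverage fields at defaults; only
#'   identity, body weight and foot area are carried by the file).
#' @export
read_subject <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("subject_id", "body_weight_N", "foot_area_cm2")) {
    if (is.null(meta[[field]])) {
      stop("subject file ", path, " is missing field '", field, "'",
           call. = FALSE)
    }
  }
  subject_model(subject_id = meta$subject_id,
                body_weight = meta$body_weight_N,
                foot_area = meta$foot_area_cm2)
}

#' Read a walking trial from CSV/JSON files
#'
#' Validates required columns, timestamp monotonicity and resistance
#' positivity, reporting the first offending line on failure.
#'
#' @param fp_csv Force-plate CSV (`t_s,fx_N,fy_N,fz_N`).
#' @param ips_csv Insole CSV (`t_s,r_hind_ohm,r_fore_ohm`).
#' @param subject_json Subject metadata JSON.
#' @param speed Walking speed label (m/s), stored on the trial.
#' @return A `walking_trial` (without generator ground truth).
#' @export
read_trial <- function(fp_csv, ips_csv, subject_json, speed = NA_real_) {
  subject <- read_subject(subject_json)
  fp_df <- utils::read.csv(fp_csv)
  check_columns(fp_df, c("t_s", "fx_N", "fy_N", "fz_N"), fp_csv)
  check_monotone(fp_df$t_s, fp_csv)
  ips_df <- utils::read.csv(ips_csv)
  check_columns(ips_df, c("t_s", "r_hind_ohm", "r_fore_ohm"), ips_csv)
  check_monotone(ips_df$t_s, ips_csv)
  for (col in c("r_hind_ohm", "r_fore_ohm")) {
    bad <- which(ips_df[[col]] <= 0)
    if (length(bad)) {
      stop("non-positive resistance in ", ips_csv, " column ", col,
           " at line ", bad[1L] + 1L, call. = FALSE)
    }
  }
  mk <- function(t, v, unit) sampled_signal(t, v, unit,
                                            subject_id = subject$subject_id)
  fx <- mk(fp_df$t_s, fp_df$fx_N, "N")
  fy <- mk(fp_df$t_s, fp_df$fy_N, "N")
  fz <- mk(fp_df$t_s, fp_df$fz_N, "N")
  structure(
    list(fp_force = resultant_force(fx, fy, fz),
         ips_hind = mk(ips_df$t_s, ips_df$r_hind_ohm, "ohm"),
         ips_fore = mk(ips_df$t_s, ips_df$r_fore_ohm, "ohm"),
         speed = speed, duration = diff(range(fp_df$t_s)),
         subject = subject, truth = NULL),
    class = "walking_trial"
  )
}

check_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

check_monotone <- function(t, path) {
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stop("timestamps in ", path, " are not strictly increasing at line ",
         bad[1L] + 2L, call. = FALSE)  # +1 header, +1 second of the pair
  }
}

#' Condition one walking trial and extract per-cycle peak data
#'
#' Runs the per-trial measurement chain: stomp synchronization of the
#' insole clock, resampling of each resistance channel to the force-plate
#' rate, binomial smoothing, per-sensor calibrated force, baseline force
#' zeroing over unloaded spans, swing clamping, force-plate filtering and
#' heel-strike detection, and gait-cycle segmentation. Cycles are taken
#' from the force-plate heel strikes after the stomp transient; for each
#' cycle the force-plate two peaks (and the hind/fore sensor forces at
#' those instants, which feed the total-force fit) and the per-cycle
#' maxima are recorded.
#'
#' @param trial A `walking_trial`.
#' @param cal_hind,cal_fore `sensor_calibration` objects.
#' @param config A `run_config`.
#' @return List with conditioned signals (`fp` %BW, `f_hind`, `f_fore`
#'   %BW on the force-plate grid), `cycles` (`gait_cycles`), and
#'   `peak_rows` (data frame: per cycle, `F_fp`, `F_hind`, `F_fore` at the
#'   two force-plate peaks plus the per-cycle `fp_max`, all %BW).
#' @export
process_walking_trial <- function(trial, cal_hind, cal_fore,
                                  config = run_config()) {
  bw <- trial$subject$body_weight
  fp <- butterworth_lowpass(trial$fp_force, config$fp_cutoff_hz,
                            config$fp_order)
  offset <- synchronize_stomp(trial$ips_hind, fp)
  condition <- function(raw, cal) {
    shifted <- sampled_signal(raw$timestamps - offset, raw$values, "ohm",
                              subject_id = raw$subject_id)
    r <- resample_uniform(shifted, config$ips_resample_hz)
    r <- binomial_filter(r, config$ips_binomial_n)
    unloaded <- detect_unloaded(r, config$baseline_frac)
    f <- apply_sensor_calibration(r, cal)
    f <- zero_baseline(f, reference = r,
                       baseline_frac = config$baseline_frac)
    f <- clamp_swing(f, unloaded)
    normalize_bw(with_values(f, pmax(f$values, 0)), bw)
  }
  f_hind <- condition(trial$ips_hind, cal_hind)
  f_fore <- condition(trial$ips_fore, cal_fore)
  fp_pbw <- normalize_bw(fp, bw)
  hs <- detect_hs_fp(fp, config$hs_threshold_n, config$hs_debounce_s)
  stomp_t <- fp_stomp_onset(fp)
  hs <- hs[hs > stomp_t + 1]
  if (length(hs) < 3L) {
    stop("trial has too few heel strikes after the stomp", call. = FALSE)
  }
  cycles <- segment_cycles(hs)
  at <- function(sig, times) {
    stats::approx(sig$timestamps, sig$values, xout = times, rule = 2)$y
  }
  rows <- lapply(seq_len(nrow(cycles)), function(i) {
    sel <- fp_pbw$timestamps >= cycles$start[i] &
      fp_pbw$timestamps < cycles$end[i]
    t_c <- fp_pbw$timestamps[sel]
    pk <- extract_2pk(t_c, fp_pbw$values[sel], "fp",
                      config$peak_split_pct, config$peak_min_width_s)
    data.frame(cycle = i,
               F_fp = c(pk$pk1, pk$pk2),
               t_peak = c(pk$t1, pk$t2),
               F_hind = at(f_hind, c(pk$t1, pk$t2)),
               F_fore = at(f_fore, c(pk$t1, pk$t2)),
               fp_max = extract_max(fp_pbw$values[sel]))
  })
  list(fp = fp_pbw, f_hind = f_hind, f_fore = f_fore, cycles = cycles,
       offset = offset, peak_rows = do.call(rbind, rows))
}

#' Agreement analyses for a test fold given a total-force calibration
#'
#' Forms the total insole force on each test trial, extracts per-cycle
#' peaks from both instruments (force plate by the 30% split; insole by
#' the two widest-than-0.05-s largest peaks) and per-cycle maxima, pools
#' cycles over the fold and runs the Bland-Altman analysis for the
#' two-peak (`twopk`) and maximum (`max`) assessments. Insole cycles
#' without two qualifying peaks are excluded from `twopk` only; dropped
#' cycle counts are reported.
#'
#' @param processed List of processed trials (from
#'   [process_walking_trial()]).
#' @param tf_cal A `total_force_calibration`.
#' @param config A `run_config`.
#' @return Named list of `bland_altman` results (`twopk`, `max`) with an
#'   attribute `"dropped_2pk_cycles"`.
#' @export
fold_agreement <- function(processed, tf_cal, config = run_config()) {
  twopk_ips <- twopk_fp <- max_ips <- max_fp <- numeric(0)
  dropped <- 0L
  for (pr in processed) {
    ips_total <- total_force(pr$f_hind, pr$f_fore, tf_cal)
    for (i in seq_len(nrow(pr$cycles))) {
      sel <- ips_total$timestamps >= pr$cycles$start[i] &
        ips_total$timestamps < pr$cycles$end[i]
      t_c <- ips_total$timestamps[sel]
      v_ips <- ips_total$values[sel]
      fp_rows <- pr$peak_rows[pr$peak_rows$cycle == i, ]
      pk_ips <- extract_2pk(t_c, v_ips, "ips",
                            config$peak_split_pct,
                            config$peak_min_width_s)
      if (is.na(pk_ips$pk1)) {
        dropped <- dropped + 1L
      } else {
        twopk_ips <- c(twopk_ips, pk_ips$pk1, pk_ips$pk2)
        twopk_fp <- c(twopk_fp, fp_rows$F_fp)
      }
      max_ips <- c(max_ips, extract_max(v_ips))
      max_fp <- c(max_fp, fp_rows$fp_max[1L])
    }
  }
  out <- list(twopk = bland_altman(twopk_ips, twopk_fp),
              max = bland_altman(max_ips, max_fp))
  attr(out, "dropped_2pk_cycles") <- dropped
  out
}

#' Run the full validation pipeline for one synthetic subject
#'
#' Generates (or accepts) the study protocol for one subject -- two step
#' calibration trials and six 30-s walking trials (two repetitions at
#' 0.5, 1.0 and 1.5 m/s) -- then: fits both per-sensor calibrations,
#' conditions every walking trial, runs the stratified two-fold
#' cross-validation (8 iterations; each refits the total-force scaling on
#' its calibration fold and evaluates both agreement assessments on its
#' test fold), selects the representative iteration, and simulates PWB
#' overload detection from the representative maximum-force error model.
#'
#' @param subject A `subject_model`.
#' @param config A `run_config`.
#' @param noise Logical; sensor noise on/off for the generated trials.
#' @param peak_sd Per-cycle peak variation (%BW) for the generated trials.
#' @param out_dir Optional directory; if given, tidy result CSVs and a
#'   run log are written there.
#' @return An object of class `pipeline_result`: list with `sensor_cals`,
#'   `cv` (a `cv_result`), `representative` (iteration index),
#'   `tf_cal_full` (total-force calibration fitted on all trials),
#'   `pwb` (Monte-Carlo + analytic results), `results` (tidy per-iteration
#'   data frame), and `config`.
#' @export
run_pipeline <- function(subject = subject_model(), config = run_config(),
                         noise = TRUE, peak_sd = 4, out_dir = NULL) {
  seed <- config$seed
  cal_hind <- calibrate_sensor(
    generate_calibration_trial(subject, "hind", seed = seed, noise = noise),
    step = config$resistance_step_ohm)
  cal_fore <- calibrate_sensor(
    generate_calibration_trial(subject, "fore", seed = seed + 1L,
                               noise = noise),
    step = config$resistance_step_ohm)
  grid <- expand.grid(rep = seq_len(config$reps), speed = config$speeds)
  trials <- lapply(seq_len(nrow(grid)), function(i) {
    generate_walking_trial(
      subject, grid$speed[i], seed = seed + 10L * i,
      duration = config$duration_s,
      clock_offset = 0.05 * i, noise = noise, peak_sd = peak_sd)
  })
  processed <- lapply(trials, process_walking_trial,
                      cal_hind = cal_hind, cal_fore = cal_fore,
                      config = config)
  analysis_fn <- function(cal_pr, test_pr) {
    tf <- fit_total_force(do.call(rbind, lapply(cal_pr, `[[`,
                                                "peak_rows")),
                          subject_id = subject$subject_id)
    res <- fold_agreement(test_pr, tf, config)
    res$tf_cal <- tf
    res
  }
  cv <- stratified_two_fold_cv(processed, grid$speed, analysis_fn)
  rep_idx <- select_representative_subset(cv, "max")
  rep_ba <- cv$iterations[[rep_idx]]$max
  tf_full <- fit_total_force(
    do.call(rbind, lapply(processed, `[[`, "peak_rows")),
    subject_id = subject$subject_id)
  pwb <- pwb_from_agreement(rep_ba, mu_f = config$pwb_mu,
                            sigma_f = config$pwb_sigma,
                            limit = config$pwb_limit,
                            n_draws = config$pwb_n, seed = seed)
  results <- do.call(rbind, lapply(seq_along(cv$iterations), function(i) {
    do.call(rbind, lapply(c("twopk", "max"), function(a) {
      ba <- cv$iterations[[i]][[a]]
      data.frame(subject = subject$subject_id, assessment = a,
                 iteration = i, n_pairs = ba$n_pairs,
                 mod_pbw = ba$mod, two_s_pbw = ba$two_s,
                 p_value = ba$p_value, slope = ba$slope,
                 intercept = ba$intercept, resid_sd = ba$resid_sd,
                 c_hind = cv$iterations[[i]]$tf_cal$c_hind,
                 c_fore = cv$iterations[[i]]$tf_cal$c_fore,
                 foot_area_cm2 = subject$foot_area)
    }))
  }))
  out <- structure(
    list(sensor_cals = list(hind = cal_hind, fore = cal_fore),
         cv = cv, representative = rep_idx, tf_cal_full = tf_full,
         pwb = pwb, results = results, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "agreement_results.csv"),
                     row.names = FALSE)
    log_lines <- c(
      sprintf("subject: %s", subject$subject_id),
      sprintf("seed: %d", seed),
      sprintf("config: %s",
              paste(names(config), vapply(config, function(x)
                paste(format(x), collapse = "/"), character(1)),
                sep = "=", collapse = " ")),
      sprintf("representative_iteration: %d", rep_idx))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$cv$summary, row.names = FALSE)
  cat(sprintf("  representative iteration: %d\n", x$representative))
  cat(sprintf("  total-force coefficients (all trials): %.3f, %.3f\n",
              x$tf_cal_full$c_hind, x$tf_cal_full$c_fore))
  print(x$pwb$mc)
  invisible(x)
}
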