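# Shared fixtures, built in code and cached for the duration of a test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

default_subject <- function() subject_model()

# a noise-free walking trial with identical cycles and a 0.37 s clock offset
clean_trial <- function() {
  fixture("clean_trial", generate_walking_trial(
    default_subject(), speed = 1.0, seed = 42L, clock_offset = 0.37,
    noise = FALSE, peak_sd = 0))
}

# noise-free per-sensor calibrations for the default subject
clean_cals <- function() {
  fixture("clean_cals", {
    s <- default_subject()
    list(
      hind = calibrate_sensor(
        generate_calibration_trial(s, "hind", seed = 7L, noise = FALSE)),
      fore = calibrate_sensor(
        generate_calibration_trial(s, "fore", seed = 8L, noise = FALSE)))
  })
}

# one full-protocol pipeline run (noisy, 30-s trials) shared by the
# deeper end-to-end checks
full_pipeline_result <- function() {
  fixture("full_pipeline", run_pipeline(
    default_subject(), run_config(pwb_n = 2e5, seed = 101L),
    noise = TRUE, peak_sd = 4))
}
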