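#' Timestamped scalar signal
#'
#' The basic container used throughout the package: a vector of strictly
#' increasing timestamps paired with a vector of values carrying a unit tag.
#' Force-plate records are uniformly sampled (typically 2,000 Hz); raw insole
#' resistance records are irregular (nominally 28 Hz with timestamp jitter).
#'
#' @param timestamps Numeric vector of times in seconds, strictly increasing.
#' @param values Numeric vector, same length as `timestamps`.
#' @param unit One of `"N"` (newtons), `"%BW"` (percent body weight) or
#'   `"ohm"` (sensor resistance).
#' @param nominal_rate Sampling rate in Hz, or `"irregular"` for jittered
#'   records. If `NULL` it is inferred: a constant timestamp increment (to
#'   within 1e-9 s) gives a uniform rate, anything else is irregular.
#' @param subject_id Optional identifier used to guard against applying one
#'   subject's calibration to another subject's data.
#'
#' @return An object of class `sampled_signal`: a list with elements
#'   `timestamps`, `values`, `unit`, `nominal_rate`, `subject_id`.
#' @export
#' @examples
#' s <- sampled_signal(seq(0, 1, by = 0.01), sin(seq(0, 1, by = 0.01)), "N")
#' s$nominal_rate
sampled_signal <- function(timestamps, values, unit = c("N", "%BW", "ohm"),
                           nominal_rate = NULL, subject_id = NULL) {
  unit <- match.arg(unit)
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values)) {
    stop("timestamps and values must have the same length", call. = FALSE)
  }
  if (anyNA(timestamps) || (length(timestamps) > 1L &&
                            any(diff(timestamps) <= 0))) {
    stop("timestamps must be finite and strictly increasing", call. = FALSE)
  }
  if (is.null(nominal_rate)) {
    nominal_rate <- infer_rate(timestamps)
  }
  structure(
    list(timestamps = timestamps, values = values, unit = unit,
         nominal_rate = nominal_rate, subject_id = subject_id),
    class = "sampled_signal"
  )
}

infer_rate <- function(timestamps) {
  if (length(timestamps) < 2L) return("irregular")
  d <- diff(timestamps)
  if (max(d) - min(d) < 1e-9) 1 / mean(d) else "irregular"
}

#' @export
print.sampled_signal <- function(x, ...) {
  rate <- if (identical(x$nominal_rate, "irregular")) {
    sprintf("irregular (~%.1f Hz)", (length(x$timestamps) - 1) /
              diff(range(x$timestamps)))
  } else {
    sprintf("%.6g Hz", x$nominal_rate)
  }
  cat(sprintf("<sampled_signal> %d samples [%s], %s, %.3f..%.3f s\n",
              length(x$values), x$unit, rate,
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

is_uniform <- function(sig) !identical(sig$nominal_rate, "irregular")

stopifnot_uniform <- function(sig, what) {
  if (!is_uniform(sig)) {
    stop(what, " requires a uniformly sampled signal; resample first",
         call. = FALSE)
  }
}

stopifnot_same_grid <- function(...) {
  sigs <- list(...)
  t0 <- sigs[[1L]]$timestamps
  for (s in sigs[-1L]) {
    if (length(s$timestamps) != length(t0) ||
        max(abs(s$timestamps - t0)) > 1e-9) {
      stop("signals must share identical timestamps", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# unit-tag discipline: operations combining force signals insist on a common
# unit so N and %BW are never silently mixed
stopifnot_same_unit <- function(...) {
  units <- vapply(list(...), function(s) s$unit, character(1))
  if (length(unique(units)) != 1L) {
    stop("signals have mixed units (", paste(units, collapse = ", "),
         "); convert before combining", call. = FALSE)
  }
  invisible(TRUE)
}

with_values <- function(sig, values, unit = sig$unit) {
  sampled_signal(sig$timestamps, values, unit,
                 nominal_rate = sig$nominal_rate,
                 subject_id = sig$subject_id)
}

#' Resultant (Euclidean norm) of three force components
#'
#' Collapses the three orthogonal force-plate channels into the resultant
#' ground reaction force, the quantity the insole is calibrated against.
#'
#' @param fx,fy,fz `sampled_signal` force components sharing timestamps and
#'   unit.
#' @return A non-negative `sampled_signal` with the same timestamps and unit.
#' @export
resultant_force <- function(fx, fy, fz) {
  stopifnot_same_grid(fx, fy, fz)
  stopifnot_same_unit(fx, fy, fz)
  with_values(fx, sqrt(fx$values^2 + fy$values^2 + fz$values^2))
}

#' Normalize a force signal to percent body weight
#'
#' @param force A `sampled_signal` in newtons.
#' @param body_weight Subject body weight in newtons (> 0).
#' @return The signal rescaled to `%BW` (100 = one body weight).
#' @export
normalize_bw <- function(force, body_weight) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("body_weight must be a positive scalar in newtons", call. = FALSE)
  }
  if (force$unit != "N") stop("normalize_bw expects a signal in N",
                              call. = FALSE)
  with_values(force, force$values * 100 / body_weight, unit = "%BW")
}

#' Convert a percent-body-weight signal back to newtons
#'
#' @inheritParams normalize_bw
#' @param force A `sampled_signal` in `%BW`.
#' @return The signal in newtons.
#' @export
denormalize_bw <- function(force, body_weight) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("body_weight must be a positive scalar in newtons", call. = FALSE)
  }
  if (force$unit != "%BW") stop("denormalize_bw expects a signal in %BW",
                                call. = FALSE)
  with_values(force, force$values * body_weight / 100, unit = "N")
}
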