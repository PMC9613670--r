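#' Signal containers
#'
#' Lightweight S3 containers used throughout the pipeline. A
#' `kinematic_signal` carries a per-frame (or resampled) displacement series;
#' a `rate_signal` carries an instantaneous firing-rate series; a
#' `voltage_trace` carries raw or filtered microelectrode voltage; a
#' `spike_train` carries threshold-crossing timestamps (sample indices).
#'
#' @param values numeric vector of samples. `NA` marks absent samples
#'   (allowed only at early kinematic stages).
#' @param fs sampling rate in Hz.
#' @param stage processing stage tag.
#' @param source_landmarks character vector of landmark names the signal was
#'   derived from.
#' @param flags optional logical vector marking repaired samples (QC).
#' @return An object of the corresponding class.
#' @name signal-containers
NULL

#' @rdname signal-containers
#' @export
kinematic_signal <- function(values, fs,
                             stage = c("raw_displacement", "repaired",
                                       "smoothed", "resampled", "normalized"),
                             source_landmarks = character(), flags = NULL) {
  stage <- match.arg(stage)
  assert_that(is.numeric(values), "nmmap_validation_error",
              "kinematic values must be numeric")
  assert_that(is_scalar_number(fs) && fs > 0, "nmmap_validation_error",
              "fs must be a positive number")
  if (stage != "raw_displacement" && anyNA(values))
    stop_nmmap("nmmap_validation_error",
               "absent samples are not allowed at stage '%s'", stage)
  structure(list(values = as.numeric(values), fs = fs, stage = stage,
                 source_landmarks = source_landmarks, flags = flags),
            class = "kinematic_signal")
}

#' @rdname signal-containers
#' @export
rate_signal <- function(values, fs = 1200, stage = c("rate", "normalized")) {
  stage <- match.arg(stage)
  assert_that(is.numeric(values) && !anyNA(values), "nmmap_validation_error",
              "rate values must be numeric and complete")
  if (stage == "rate")
    assert_that(all(values >= 0), "nmmap_validation_error",
                "firing rates must be non-negative")
  structure(list(values = as.numeric(values), fs = fs, stage = stage),
            class = "rate_signal")
}

#' @rdname signal-containers
#' @param samples numeric vector of voltage samples (microvolts).
#' @export
voltage_trace <- function(samples, fs) {
  assert_that(is.numeric(samples) && !anyNA(samples),
              "nmmap_validation_error", "voltage samples must be numeric")
  assert_that(is_scalar_number(fs) && fs > 0, "nmmap_validation_error",
              "fs must be a positive number")
  # the 100-4000 Hz MUA bandpass needs the upper edge below Nyquist
  assert_that(fs > 8000, "nmmap_validation_error",
              "fs = %g Hz too low: the 4000 Hz bandpass edge requires fs > 8000",
              fs)
  structure(list(samples = as.numeric(samples), fs = fs,
                 duration_s = length(samples) / fs),
            class = "voltage_trace")
}

#' @rdname signal-containers
#' @param timestamps strictly increasing spike sample indices (0-based).
#' @param threshold_used detection threshold as a multiple of `sd_bn`.
#' @param sd_bn background-noise SD estimate (microvolts).
#' @param duration_s recording duration in seconds (for the mean rate).
#' @export
spike_train <- function(timestamps, fs, threshold_used = NA_real_,
                        sd_bn = NA_real_, duration_s = NULL) {
  timestamps <- as.numeric(timestamps)
  assert_that(!is.unsorted(timestamps, strictly = TRUE),
              "nmmap_validation_error",
              "spike timestamps must be strictly increasing")
  if (is.null(duration_s))
    duration_s <- if (length(timestamps)) (max(timestamps) + 1) / fs else 0
  mean_rate <- if (duration_s > 0) length(timestamps) / duration_s else 0
  structure(list(timestamps = timestamps, fs = fs,
                 threshold_used = threshold_used, sd_bn = sd_bn,
                 duration_s = duration_s, mean_rate_hz = mean_rate),
            class = "spike_train")
}

#' Min-max normalize a signal to the unit interval
#'
#' Rescales a series to `(v - min) / (max - min)`, the common scale on which
#' kinematic and firing-rate signals are compared. Constant input is
#' degenerate (the scale is undefined) and raises an error so the caller can
#' skip the epoch.
#'
#' @param x a `kinematic_signal`, `rate_signal`, or bare numeric vector.
#' @return Object of the same type, normalized; stage is set to
#'   `"normalized"` for signal containers.
#' @examples
#' normalize_01(c(2, 4, 6))
#' @export
normalize_01 <- function(x) UseMethod("normalize_01")

#' @export
normalize_01.numeric <- function(x) {
  assert_that(!anyNA(x), "nmmap_validation_error",
              "cannot normalize a series with absent values")
  rng <- range(x)
  assert_that(rng[2] > rng[1], "nmmap_degenerate_error",
              "constant series: min-max normalization undefined")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' @export
normalize_01.kinematic_signal <- function(x) {
  out <- x
  out$values <- normalize_01(x$values)
  out$stage <- "normalized"
  out
}

#' @export
normalize_01.rate_signal <- function(x) {
  out <- x
  out$values <- normalize_01(x$values)
  out$stage <- "normalized"
  out
}

#' @export
print.kinematic_signal <- function(x, ...) {
  cat(sprintf("<kinematic_signal> %d samples @ %g Hz, stage=%s\n",
              length(x$values), x$fs, x$stage))
  if (length(x$source_landmarks))
    cat("  landmarks:", paste(x$source_landmarks, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.rate_signal <- function(x, ...) {
  cat(sprintf("<rate_signal> %d samples @ %g Hz, stage=%s\n",
              length(x$values), x$fs, x$stage))
  invisible(x)
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$fs, x$duration_s))
  invisible(x)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf(
    "<spike_train> %d spikes @ %g Hz, mean rate %.1f Hz, k=%s, SD_bn=%s\n",
    length(x$timestamps), x$fs, x$mean_rate_hz,
    format(x$threshold_used), format(signif(x$sd_bn, 4))))
  invisible(x)
}
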