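#' Bandpass filter a voltage trace for MUA extraction
#'
#' Zero-phase (forward-backward) Butterworth bandpass, by default 2nd order
#' between 100 and 4000 Hz with edges normalized to the Nyquist frequency.
#' The forward-backward pass doubles the effective order and removes phase
#' lag, so spike timing is preserved. An optional 60 Hz notch (off by
#' default) can precede the bandpass for recordings with heavy line noise.
#'
#' @param trace a [voltage_trace()].
#' @param band_hz length-2 passband in Hz (default `c(100, 4000)`).
#' @param order Butterworth design order before the forward-backward pass
#'   (default 2).
#' @param notch_60 apply a 60 Hz notch first (default `FALSE`).
#' @return A filtered [voltage_trace()] of the same length.
#' @export
bandpass_mua <- function(trace, band_hz = c(100, 4000), order = 2,
                         notch_60 = FALSE) {
  stopifnot(inherits(trace, "voltage_trace"))
  assert_that(band_hz[1] > 0 && band_hz[1] < band_hz[2] &&
                band_hz[2] < trace$fs / 2, "nmmap_validation_error",
              "passband (%g, %g) invalid for fs = %g",
              band_hz[1], band_hz[2], trace$fs)
  warmup <- 3 * (2 * order + 1)
  assert_that(length(trace$samples) >= 3 * warmup, "nmmap_validation_error",
              "trace too short for filtering (%d samples < %d)",
              length(trace$samples), 3 * warmup)
  v <- trace$samples - mean(trace$samples)
  # reflective padding keeps the forward-backward startup transient (time
  # constant ~1/band_low) out of the epoch
  n <- length(v)
  pad <- min(n - 1L, as.integer(round(6 * trace$fs / band_hz[1])))
  vp <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[n] - v[(n - 1):(n - pad)])
  if (notch_60) {
    notch <- signal::butter(2, c(58, 62) / (trace$fs / 2), type = "stop")
    vp <- signal::filtfilt(notch, vp)
  }
  bp <- signal::butter(order, band_hz / (trace$fs / 2), type = "pass")
  out <- signal::filtfilt(bp, vp)[(pad + 1):(pad + n)]
  voltage_trace(out, trace$fs)
}

#' Robust background-noise SD estimate
#'
#' `SD_bn = median(|v|) / 0.6745`: under a Gaussian noise model the median
#' absolute value equals 0.6745 SD, and unlike the sample SD this estimate
#' is not inflated by high-rate spiking riding on the noise.
#'
#' @param filtered a bandpassed [voltage_trace()] or numeric vector.
#' @return Noise SD in the trace's units (microvolts).
#' @export
estimate_noise_sd <- function(filtered) {
  v <- if (inherits(filtered, "voltage_trace")) filtered$samples
       else as.numeric(filtered)
  assert_that(length(v) > 0, "nmmap_validation_error", "empty trace")
  median(abs(v)) / 0.6745
}

#' Noise-adaptive multi-unit spike detection
#'
#' Spikes are rising crossings of the rectified filtered signal above
#' `k * SD_bn`, with no inter-spike interval imposed (multi-unit activity
#' is deliberately kept unsorted). The multiplier `k` starts at `start_k`
#' and walks in steps of `step` within `k_range` until the mean crossing
#' rate falls strictly inside `rate_bounds_hz` — below the lower bound the
#' threshold is lowered, above the upper bound it is raised — or a range
#' limit is reached, in which case the limit's `k` is kept. The bounds
#' reflect expected subthalamic firing (80-125 Hz per unit, 1-3 units per
#' recording site).
#'
#' @param filtered a bandpassed [voltage_trace()].
#' @param start_k initial threshold multiplier (default 4.5).
#' @param k_range allowed multiplier range (default `c(2.5, 6.5)`).
#' @param rate_bounds_hz acceptable mean crossing-rate interval, strict on
#'   both sides (default `c(80, 400)`).
#' @param step multiplier step (default 0.1).
#' @param polarity `"absolute"` (default; crossings of `|v|`, capturing both
#'   spike polarities) or `"negative"` (crossings of `-v`).
#' @return A [spike_train()] with `threshold_used` and `sd_bn` recorded.
#' @export
detect_spikes_adaptive <- function(filtered, start_k = 4.5,
                                   k_range = c(2.5, 6.5),
                                   rate_bounds_hz = c(80, 400), step = 0.1,
                                   polarity = c("absolute", "negative")) {
  stopifnot(inherits(filtered, "voltage_trace"))
  polarity <- match.arg(polarity)
  v <- filtered$samples
  assert_that(length(v) > 0, "nmmap_validation_error", "zero-length trace")
  sd_bn <- estimate_noise_sd(v)
  rect <- if (polarity == "absolute") abs(v) else -v
  dur <- filtered$duration_s

  crossings <- function(k) {
    thr <- k * sd_bn
    above <- rect > thr
    which(above & !c(FALSE, above[-length(above)])) - 1L  # 0-based
  }
  rate_of <- function(ts) length(ts) / dur
  in_bounds <- function(r) r > rate_bounds_hz[1] && r < rate_bounds_hz[2]

  k <- start_k
  ts <- crossings(k)
  r <- rate_of(ts)
  if (!in_bounds(r)) {
    dir <- if (r <= rate_bounds_hz[1]) -1 else 1
    limit <- if (dir < 0) k_range[1] else k_range[2]
    while (!in_bounds(r) && abs(k - limit) > 1e-9) {
      k <- if (dir < 0) max(limit, k - step) else min(limit, k + step)
      ts <- crossings(k)
      r <- rate_of(ts)
    }
  }
  spike_train(ts, filtered$fs, threshold_used = k, sd_bn = sd_bn,
              duration_s = dur)
}

#' Downsample spike timestamps to the common rate
#'
#' Timestamps at the acquisition rate are divided by `fs / fs_out` (44/1.2
#' for the standard 44 kHz to 1200 Hz path) and rounded to the nearest
#' integer; when several spikes collapse onto one downsampled timestamp,
#' only one representation is retained.
#'
#' @param spikes a [spike_train()].
#' @param fs_out target rate in Hz (default 1200).
#' @return A [spike_train()] at `fs_out`.
#' @export
downsample_timestamps <- function(spikes, fs_out = 1200) {
  stopifnot(inherits(spikes, "spike_train"))
  factor <- spikes$fs / fs_out
  ts <- unique(round(spikes$timestamps / factor))
  spike_train(ts, fs_out, threshold_used = spikes$threshold_used,
              sd_bn = spikes$sd_bn, duration_s = spikes$duration_s)
}

#' Instantaneous firing rate at the common sampling grid
#'
#' For each sample point the rate is the reciprocal of the inter-spike
#' interval surrounding it: with consecutive spikes at samples `t_i <= s <
#' t_{i+1}`, `rate(s) = fs / (t_{i+1} - t_i)` Hz. Samples before the first
#' spike and after the last hold the nearest defined interval's rate. With
#' fewer than two spikes the rate is identically zero and a QC warning is
#' attached.
#'
#' @param spikes a [spike_train()] at the common rate (1200 Hz).
#' @param n_samples length of the output grid (samples `0..n_samples-1`).
#' @return A [rate_signal()] at stage `"rate"`.
#' @export
instantaneous_rate <- function(spikes, n_samples) {
  stopifnot(inherits(spikes, "spike_train"))
  assert_that(is_scalar_number(n_samples) && n_samples > 0,
              "nmmap_validation_error", "n_samples must be positive")
  n_samples <- as.integer(n_samples)
  ts <- spikes$timestamps
  if (length(ts) < 2) {
    warning("fewer than 2 spikes: instantaneous rate is identically zero",
            call. = FALSE)
    return(rate_signal(rep(0, n_samples), spikes$fs, stage = "rate"))
  }
  ivl_rate <- spikes$fs / diff(ts)
  s <- seq_len(n_samples) - 1L
  i <- findInterval(s, ts)
  i <- pmin(pmax(i, 1L), length(ivl_rate))  # hold edges
  rate_signal(ivl_rate[i], spikes$fs, stage = "rate")
}

#' Normalize a firing-rate signal to the unit interval
#'
#' The firing-rate counterpart of the kinematic min-max normalization, so
#' both signals share a common unitless scale before comparison (shared
#' implementation with [normalize_01()]).
#'
#' @param sig a [rate_signal()].
#' @return A stage-`"normalized"` [rate_signal()].
#' @export
normalize_rate <- function(sig) {
  stopifnot(inherits(sig, "rate_signal"))
  normalize_01(sig)
}

#' Full MUA processing path
#'
#' Convenience wrapper: bandpass, adaptive detection, timestamp
#' downsampling, instantaneous rate, normalization.
#'
#' @param trace raw [voltage_trace()].
#' @param n_samples output grid length; defaults to
#'   `round(n * fs_out / fs)`.
#' @param fs_out common rate (default 1200).
#' @param normalize return the normalized signal (default `TRUE`); set
#'   `FALSE` to obtain the rate in Hz.
#' @param ... passed to [bandpass_mua()] and [detect_spikes_adaptive()].
#' @return A [rate_signal()]; the spike train and filter settings are
#'   attached as attribute `"spikes"`.
#' @export
process_mua <- function(trace, n_samples = NULL, fs_out = 1200,
                        normalize = TRUE, ...) {
  dots <- list(...)
  bp_args <- dots[intersect(names(dots), c("band_hz", "order", "notch_60"))]
  det_args <- dots[intersect(names(dots),
                             c("start_k", "k_range", "rate_bounds_hz",
                               "step", "polarity"))]
  filtered <- do.call(bandpass_mua, c(list(trace), bp_args))
  spikes <- do.call(detect_spikes_adaptive, c(list(filtered), det_args))
  ds <- downsample_timestamps(spikes, fs_out)
  if (is.null(n_samples))
    n_samples <- round(length(trace$samples) * fs_out / trace$fs)
  r <- instantaneous_rate(ds, n_samples)
  out <- if (normalize && diff(range(r$values)) > 0) normalize_rate(r) else r
  attr(out, "spikes") <- ds
  out
}
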