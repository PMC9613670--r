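#' Frame-to-frame fingertip displacement
#'
#' Kinematic information is the frame-to-frame Euclidean distance of a
#' tracked landmark in 2-D pixel space:
#' `d[t] = sqrt((x[t]-x[t-1])^2 + (y[t]-y[t-1])^2)` for `t = 2..n`, giving a
#' series of length `n - 1` at the video frame rate. Detections with
#' likelihood below `likelihood_min` are treated as absent; any displacement
#' involving an absent frame propagates as absent (`NA`) and is repaired
#' later by [repair_artifacts()].
#'
#' @param track a [keypoint_table()].
#' @param landmark landmark name.
#' @param likelihood_min minimum tracking likelihood; lower detections are
#'   gated out as absent (default 0.6).
#' @return A [kinematic_signal()] at stage `"raw_displacement"`.
#' @export
frame_displacement <- function(track, landmark, likelihood_min = 0.6) {
  stopifnot(inherits(track, "keypoint_table"))
  assert_that(landmark %in% track$landmarks, "nmmap_lookup_error",
              "unknown landmark '%s'", landmark)
  assert_that(track$n_frames >= 2, "nmmap_validation_error",
              "need at least 2 frames for displacement")
  x <- track$x[, landmark]
  y <- track$y[, landmark]
  lk <- track$likelihood[, landmark]
  gate <- is.na(lk) | lk < likelihood_min
  x[gate] <- NA
  y[gate] <- NA
  d <- sqrt(diff(x)^2 + diff(y)^2)
  kinematic_signal(d, track$frame_rate, stage = "raw_displacement",
                   source_landmarks = landmark)
}

#' Repair tracking artifacts in a displacement series
#'
#' Temporary loss of a tracked point shows up as missing samples or
#' implausibly large displacement spikes. Samples exceeding
#' `mean + k_sd * SD` of the epoch's own displacement series (moments taken
#' over the finite samples, single pass) and all absent samples are flagged;
#' each flagged run is replaced by linear interpolation between its nearest
#' unflagged neighbours, and runs touching a series edge are filled with the
#' nearest unflagged value. The flag mask is kept for QC.
#'
#' @param sig a stage-`"raw_displacement"` [kinematic_signal()].
#' @param k_sd artifact threshold in SDs above the mean (default 4.5).
#' @return A stage-`"repaired"` [kinematic_signal()] with a `flags` mask.
#' @export
repair_artifacts <- function(sig, k_sd = 4.5) {
  stopifnot(inherits(sig, "kinematic_signal"))
  assert_that(sig$stage == "raw_displacement", "nmmap_validation_error",
              "repair_artifacts expects a raw_displacement signal")
  v <- sig$values
  n <- length(v)
  mu <- mean(v, na.rm = TRUE)
  s <- sd(v, na.rm = TRUE)
  flagged <- is.na(v) | (!is.na(s) & s > 0 & v > mu + k_sd * s)
  flagged[is.na(flagged)] <- TRUE
  assert_that(mean(flagged) <= 0.5, "nmmap_quality_error",
              "%.0f%% of samples flagged as artifact; epoch unusable",
              100 * mean(flagged))
  out <- v
  if (any(flagged)) {
    good <- which(!flagged)
    out[flagged] <- if (length(good) == 1L) v[good]
      else approx(good, v[good], xout = which(flagged),
                  rule = 2)$y  # rule=2: edge runs take nearest value
  }
  kinematic_signal(out, sig$fs, stage = "repaired",
                   source_landmarks = sig$source_landmarks, flags = flagged)
}

#' Average fingertip signals and smooth
#'
#' Averages equal-length displacement signals pointwise across landmarks
#' (in standard use: the five fingertips, the minimal set with sufficient
#' positional information), then applies a centered moving average of
#' `round(smoothing_window_s * fs)` samples. At the edges the window shrinks
#' to the available samples, so constants pass through unchanged.
#'
#' @param per_landmark list of repaired [kinematic_signal()]s with a common
#'   length and sampling rate.
#' @param smoothing_window_s smoothing window in seconds (default 0.333,
#'   i.e. 20 frames at 60 Hz).
#' @return A stage-`"smoothed"` [kinematic_signal()].
#' @export
aggregate_fingertips <- function(per_landmark, smoothing_window_s = 0.333) {
  assert_that(length(per_landmark) >= 1, "nmmap_validation_error",
              "need at least one signal")
  lens <- vapply(per_landmark, function(s) length(s$values), 0L)
  fss <- vapply(per_landmark, function(s) s$fs, 0)
  assert_that(length(unique(lens)) == 1, "nmmap_validation_error",
              "signals have mismatched lengths: %s",
              paste(unique(lens), collapse = ", "))
  assert_that(length(unique(fss)) == 1, "nmmap_validation_error",
              "signals have mismatched sampling rates")
  m <- rowMeans(do.call(cbind, lapply(per_landmark, `[[`, "values")))
  win <- max(1L, as.integer(round(smoothing_window_s * fss[1])))
  sm <- .moving_average(m, win)
  kinematic_signal(sm, fss[1], stage = "smoothed",
                   source_landmarks = unlist(lapply(per_landmark,
                                                    `[[`, "source_landmarks")))
}

# centered moving average, window shrinking at the edges; O(n) via cumsum
.moving_average <- function(x, win) {
  if (win <= 1) return(x)
  n <- length(x)
  left <- as.integer(ceiling((win - 1) / 2))
  right <- as.integer(floor((win - 1) / 2))
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Resample a kinematic signal to the common rate
#'
#' Polyphase FIR (anti-aliased) rational resampling to the common analysis
#' rate shared with the firing-rate signal. The rate change must be
#' expressible as a small-integer ratio `p/q`. The input is padded by odd
#' reflection at both ends before filtering so edge transients from the FIR
#' do not leak into the epoch.
#'
#' @param sig a stage-`"smoothed"` [kinematic_signal()] (other stages are
#'   accepted for utility use, keeping their stage semantics).
#' @param fs_out target rate in Hz (default 1200).
#' @return A stage-`"resampled"` [kinematic_signal()] of length
#'   `round(n * fs_out / fs)`.
#' @export
resample_to_common <- function(sig, fs_out = 1200) {
  stopifnot(inherits(sig, "kinematic_signal"))
  assert_that(!anyNA(sig$values), "nmmap_validation_error",
              "resampling requires a gap-free signal (run repair first)")
  pq <- .rational_ratio(fs_out / sig$fs)
  out <- .resample_padded(sig$values, pq[1], pq[2])
  kinematic_signal(out, fs_out, stage = "resampled",
                   source_landmarks = sig$source_landmarks)
}

# find small p/q for the rate ratio; error when none is exact enough
.rational_ratio <- function(ratio, max_den = 1000) {
  for (q in 1:max_den) {
    p <- ratio * q
    if (abs(p - round(p)) < 1e-9 && round(p) >= 1)
      return(c(as.integer(round(p)), as.integer(q)))
  }
  stop_nmmap("nmmap_config_error",
             "rate ratio %g is not a small-integer rational p/q", ratio)
}

.resample_padded <- function(x, p, q) {
  if (p == q) return(x)
  n <- length(x)
  pad <- min(n - 1L, 50L)
  if (pad < 1) return(rep(x, length.out = max(1L, round(n * p / q))))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::resample(c(head_pad, x, tail_pad), p, q)
  i0 <- round(pad * p / q)
  n_out <- round(n * p / q)
  as.numeric(y[(i0 + 1):(i0 + n_out)])
}
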