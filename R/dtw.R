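#' Banded dynamic time warping distance
#'
#' Classical dynamic time warping between two equal-length series with a
#' Sakoe-Chiba band: index pairings are restricted to `|i - j| <= w` with
#' `w = round(window_s * fs)` samples, local cost `|a_i - b_j|`, steps
#' (1,0), (0,1), (1,1), and boundary condition from (1,1) to (n,n). The
#' returned value is the optimal cumulative cost (the sum of
#' sample-to-sample distances along the warping path), without path-length
#' normalization: all pipeline comparisons use equal-length signals and a
#' fixed-size null, so raw sums are directly comparable. Overall signal
#' lengths are never warped onto each other; only point-to-point timing may
#' shift, within the band (200 ms by default, a deliberately liberal
#' allowance for physiologic neuro-motor latency).
#'
#' @param a,b numeric vectors (or signal containers) of equal length,
#'   normally both normalized to \[0, 1\].
#' @param window_s band half-width in seconds (default 0.2).
#' @param fs sampling rate in Hz (default 1200).
#' @param window_samples band half-width in samples; overrides `window_s`
#'   when given.
#' @return The cumulative DTW distance (non-negative scalar; 0 iff the
#'   series are identical).
#' @examples
#' dtw_distance(c(0, 0, 1, 0), c(0, 1, 0, 0), window_samples = 1)
#' @export
dtw_distance <- function(a, b, window_s = 0.2, fs = 1200,
                         window_samples = NULL) {
  a <- .signal_values(a)
  b <- .signal_values(b)
  assert_that(length(a) == length(b), "nmmap_validation_error",
              "DTW requires equal-length signals (%d vs %d)",
              length(a), length(b))
  assert_that(length(a) >= 1, "nmmap_validation_error", "empty signal")
  w <- if (!is.null(window_samples)) as.integer(window_samples)
       else as.integer(round(window_s * fs))
  assert_that(w >= 0, "nmmap_validation_error", "window must be >= 0")
  .dtw_band_cpp(as.numeric(a), as.numeric(b), w)
}

.signal_values <- function(x) {
  if (inherits(x, c("kinematic_signal", "rate_signal"))) x$values
  else as.numeric(x)
}

#' Peak lagged cross-correlation
#'
#' Confirmation metric alongside DTW: the maximum Pearson correlation
#' between the two signals over integer lags `|lag| <= max_lag_s * fs`,
#' computed on the overlapping portion at each lag. A positive lag means
#' `b` is shifted later relative to `a`.
#'
#' @param a,b equal-length numeric vectors or signal containers.
#' @param max_lag_s maximum absolute lag in seconds (default 0.2).
#' @param fs sampling rate in Hz (default 1200).
#' @return List with `peak` (maximum correlation) and `lag` (samples, at
#'   the maximum).
#' @export
crosscorr_similarity <- function(a, b, max_lag_s = 0.2, fs = 1200) {
  a <- .signal_values(a)
  b <- .signal_values(b)
  assert_that(length(a) == length(b), "nmmap_validation_error",
              "cross-correlation requires equal-length signals")
  assert_that(sd(a) > 0 && sd(b) > 0, "nmmap_degenerate_error",
              "constant input: correlation undefined")
  L <- as.integer(round(max_lag_s * fs))
  n <- length(a)
  L <- min(L, n - 2L)
  lags <- (-L):L
  cors <- vapply(lags, function(l) {
    if (l >= 0) {
      ia <- 1:(n - l); ib <- (1 + l):n
    } else {
      ia <- (1 - l):n; ib <- 1:(n + l)
    }
    sa <- a[ia]; sb <- b[ib]
    if (sd(sa) == 0 || sd(sb) == 0) return(NA_real_)
    cor(sa, sb)
  }, 0)
  best <- which.max(cors)
  list(peak = cors[best], lag = lags[best])
}
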