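#' Quantify neuro-motor similarity for one epoch
#'
#' The central estimator of the package. Given an epoch's normalized
#' kinematic signal and normalized instantaneous-firing-rate signal on the
#' common 1200 Hz grid, it computes their banded DTW distance, ranks that
#' distance within a bootstrap null distribution of `B` comparisons against
#' randomly drawn unrelated MUA segments, and classifies the epoch as
#' `quant_plus` (percentile strictly below `threshold`) or `quant_minus`.
#' The two signals are trimmed to their common length before comparison.
#'
#' @param kin normalized [kinematic_signal()].
#' @param rate normalized [rate_signal()].
#' @param db a [mua_segment_db()] for null construction.
#' @param window_s DTW band half-width in seconds (default 0.2).
#' @param B null size (default 1000).
#' @param seed integer seed for the null draws.
#' @param threshold classification threshold on the percentile (default 5).
#' @param epoch_id identifier carried into results.
#' @param movement_type,clinician_label optional epoch annotations carried
#'   into results.
#' @param exclusion,policy null-eligibility controls, see [build_null()].
#' @param fs common sampling rate (default 1200).
#' @return An object of class `nm_similarity` with components
#'   `dtw_distance`, `percentile`, `quant_label`, `null`, `crosscorr`
#'   (confirmation metric), and the inputs' metadata.
#' @seealso [build_null()], [percentile_of()], [classify_percentile()]
#' @export
nm_similarity <- function(kin, rate, db, window_s = 0.2, B = 1000,
                          seed = 1L, threshold = 5, epoch_id = "epoch",
                          movement_type = NULL, clinician_label = NULL,
                          exclusion = NULL,
                          policy = "own_window", fs = 1200) {
  kv <- .signal_values(kin)
  rv <- .signal_values(rate)
  if (inherits(kin, "kinematic_signal"))
    assert_that(kin$stage == "normalized", "nmmap_validation_error",
                "kinematic signal must be normalized")
  if (inherits(rate, "rate_signal"))
    assert_that(rate$stage == "normalized", "nmmap_validation_error",
                "rate signal must be normalized")
  n <- min(length(kv), length(rv))
  assert_that(n >= 2, "nmmap_validation_error", "signals too short")
  kv <- kv[seq_len(n)]
  rv <- rv[seq_len(n)]
  obs <- dtw_distance(kv, rv, window_s = window_s, fs = fs)
  null <- build_null(kv, db, B = B, seed = seed, exclusion = exclusion,
                     policy = policy, window_s = window_s, fs = fs)
  pct <- percentile_of(obs, null)
  cc <- tryCatch(crosscorr_similarity(kv, rv, max_lag_s = window_s, fs = fs),
                 nmmap_degenerate_error = function(e) list(peak = NA_real_,
                                                           lag = NA_integer_))
  structure(list(epoch_id = epoch_id,
                 movement_type = movement_type,
                 clinician_label = clinician_label,
                 dtw_distance = obs,
                 percentile = pct,
                 quant_label = classify_percentile(pct, threshold),
                 threshold = threshold,
                 window_s = window_s,
                 n = n, fs = fs,
                 crosscorr = cc,
                 null = null,
                 kin = kv, rate = rv),
            class = "nm_similarity")
}

#' @export
print.nm_similarity <- function(x, ...) {
  cat(sprintf("<nm_similarity> epoch %s\n", x$epoch_id))
  cat(sprintf("  DTW distance : %.1f a.u. (window %.0f ms, n = %d)\n",
              x$dtw_distance, 1000 * x$window_s, x$n))
  cat(sprintf("  percentile   : %.1f of %d null comparisons\n",
              x$percentile, x$null$B))
  cat(sprintf("  label        : %s (threshold %g)\n", x$quant_label,
              x$threshold))
  invisible(x)
}

#' @export
summary.nm_similarity <- function(object, ...) {
  nd <- object$null$distances
  out <- list(epoch_id = object$epoch_id,
              dtw_distance = object$dtw_distance,
              percentile = object$percentile,
              quant_label = object$quant_label,
              crosscorr_peak = object$crosscorr$peak,
              crosscorr_lag = object$crosscorr$lag,
              null_quantiles = quantile(nd, c(.01, .05, .25, .5, .75, .95)))
  class(out) <- "summary.nm_similarity"
  out
}

#' @export
print.summary.nm_similarity <- function(x, ...) {
  cat(sprintf("Epoch %s: DTW = %.1f a.u., percentile = %.1f, %s\n",
              x$epoch_id, x$dtw_distance, x$percentile, x$quant_label))
  cat(sprintf("Cross-correlation confirmation: peak r = %.2f at lag %d\n",
              x$crosscorr_peak, x$crosscorr_lag))
  cat("Null distance quantiles:\n")
  print(round(x$null_quantiles, 1))
  invisible(x)
}

#' Plot an epoch similarity result
#'
#' Two panels: the overlaid normalized kinematic and firing-rate signals,
#' and the null distance distribution with the observed distance marked.
#'
#' @param x an `nm_similarity` object.
#' @param ... ignored.
#' @export
plot.nm_similarity <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  t <- (seq_len(x$n) - 1) / x$fs
  plot(t, x$kin, type = "l", col = "darkorange", lwd = 1.5,
       xlab = "time (s)", ylab = "normalized amplitude",
       main = sprintf("epoch %s: kinematics vs MUA rate", x$epoch_id),
       ylim = c(0, 1))
  lines(t, x$rate, col = "steelblue")
  legend("topright", c("kinematics", "MUA rate"), lty = 1,
         col = c("darkorange", "steelblue"), bty = "n", cex = 0.8)
  h <- hist(x$null$distances, breaks = 40, plot = FALSE)
  plot(h, main = sprintf("null distribution (B = %d): percentile %.1f",
                         x$null$B, x$percentile),
       xlab = "DTW distance (a.u.)", col = "grey85", border = "grey60")
  abline(v = x$dtw_distance, col = "red", lwd = 2)
  invisible(x)
}
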