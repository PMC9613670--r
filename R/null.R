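#' MUA segment database for null construction
#'
#' The null distribution for an epoch is built from MUA segments drawn at
#' random from a database of subthalamic recordings pooled across subjects
#' and electrode depths. The database stores each recording's
#' instantaneous-rate signal at the common 1200 Hz grid (processed once
#' through the standard MUA path), plus a manifest describing provenance.
#'
#' @param rates list of stage-`"rate"` [rate_signal()]s (one per recording).
#' @param manifest data.frame with one row per recording: `recording_id`,
#'   `subject`, `depth_mm` (free-form provenance columns are kept as-is).
#' @return A `mua_segment_db`.
#' @export
mua_segment_db <- function(rates, manifest = NULL) {
  assert_that(length(rates) > 0, "nmmap_data_error", "empty database")
  ok <- vapply(rates, inherits, TRUE, what = "rate_signal")
  assert_that(all(ok), "nmmap_validation_error",
              "all database entries must be rate_signal objects")
  if (is.null(manifest))
    manifest <- data.frame(recording_id = sprintf("rec%03d",
                                                  seq_along(rates)),
                           subject = NA_character_, depth_mm = NA_real_,
                           stringsAsFactors = FALSE)
  assert_that(nrow(manifest) == length(rates), "nmmap_validation_error",
              "manifest must have one row per recording")
  names(rates) <- manifest$recording_id
  structure(list(rates = rates, manifest = manifest),
            class = "mua_segment_db")
}

#' @export
print.mua_segment_db <- function(x, ...) {
  ns <- vapply(x$rates, function(r) length(r$values), 0L)
  cat(sprintf("<mua_segment_db> %d recordings, %.1f-%.1f s @ 1200 Hz\n",
              length(x$rates), min(ns) / 1200, max(ns) / 1200))
  invisible(x)
}

#' Build a database from raw voltage recordings
#'
#' Processes each recording through the standard MUA path
#' ([process_mua()], unnormalized) once, so null draws only need slicing.
#'
#' @param traces list of [voltage_trace()]s.
#' @param manifest optional manifest data.frame (see [mua_segment_db()]).
#' @param ... passed to [process_mua()].
#' @return A `mua_segment_db`.
#' @export
build_segment_db <- function(traces, manifest = NULL, ...) {
  rates <- lapply(traces, function(tr)
    process_mua(tr, normalize = FALSE, ...))
  rates <- lapply(rates, function(r) { attr(r, "spikes") <- NULL; r })
  mua_segment_db(rates, manifest)
}

#' Bootstrap null distribution of DTW distances
#'
#' Draws `B` contiguous rate segments of the kinematic signal's length —
#' uniform over eligible recordings and uniform over start positions, with
#' replacement across draws — normalizes each to \[0, 1\] (the same path an
#' epoch's own MUA takes), and records its banded DTW distance to the
#' retained kinematic signal. Because the kinematic signal is held fixed
#' across all `B` comparisons, the resulting percentile is a well-calibrated
#' per-epoch measure. The epoch's own time window is never eligible, so an
#' observed comparison can never sit in its own null; stricter exclusions
#' (same depth / same subject) are available via `policy`.
#'
#' Draws yielding a constant segment (e.g. a silent stretch with no rate
#' structure) carry no usable comparison and are redrawn.
#'
#' @param kin normalized [kinematic_signal()] (the epoch's retained signal).
#' @param db a [mua_segment_db()].
#' @param B number of null comparisons (default 1000).
#' @param seed integer seed; the distribution is bit-reproducible from
#'   `(db, seed, kin)`.
#' @param exclusion list identifying the epoch's own source window:
#'   `recording_id`, `start`, `end` (0-based sample indices at 1200 Hz), or
#'   `NULL` when the epoch's MUA is not part of the database.
#' @param policy `"own_window"` (default), `"same_depth"`, `"same_subject"`,
#'   or `"none"`.
#' @param window_s,fs passed to [dtw_distance()].
#' @return A `null_distribution`: list with `distances` (length `B`),
#'   `seed`, `B`, `source`.
#' @export
build_null <- function(kin, db, B = 1000, seed = 1L, exclusion = NULL,
                       policy = c("own_window", "same_depth", "same_subject",
                                  "none"),
                       window_s = 0.2, fs = 1200) {
  policy <- match.arg(policy)
  stopifnot(inherits(db, "mua_segment_db"))
  kv <- .signal_values(kin)
  L <- length(kv)
  eligible <- seq_along(db$rates)
  if (!is.null(exclusion) && policy %in% c("same_depth", "same_subject")) {
    m <- db$manifest
    own <- match(exclusion$recording_id, m$recording_id)
    if (!is.na(own)) {
      drop <- if (policy == "same_depth")
        which(m$depth_mm == m$depth_mm[own] & m$subject == m$subject[own])
      else which(m$subject == m$subject[own])
      eligible <- setdiff(eligible, drop)
    }
  }
  lens <- vapply(db$rates[eligible], function(r) length(r$values), 0L)
  eligible <- eligible[lens >= L]
  assert_that(length(eligible) > 0, "nmmap_data_error",
              "no eligible recording is at least as long as the epoch (%d samples)",
              L)
  excl_rec <- if (!is.null(exclusion) && policy != "none")
    exclusion$recording_id else NULL
  w <- as.integer(round(window_s * fs))

  distances <- with_seed(seed, {
    out <- numeric(B)
    for (b in seq_len(B)) {
      drawn <- FALSE
      for (attempt in 1:100) {
        ri <- eligible[sample.int(length(eligible), 1)]
        nmax <- length(db$rates[[ri]]$values) - L
        start <- sample.int(nmax + 1L, 1) - 1L  # 0-based
        if (!is.null(excl_rec) &&
            identical(db$manifest$recording_id[ri], excl_rec) &&
            start < (exclusion$end %||% Inf) &&
            (start + L) > (exclusion$start %||% -Inf)) next  # overlaps own window
        seg <- db$rates[[ri]]$values[(start + 1):(start + L)]
        if (max(seg) - min(seg) <= 0) next  # constant segment: no structure
        out[b] <- .dtw_band_cpp(kv, (seg - min(seg)) / (max(seg) - min(seg)),
                                w)
        drawn <- TRUE
        break
      }
      if (!drawn)
        stop_nmmap("nmmap_data_error",
                   "could not draw a usable null segment after 100 attempts")
    }
    out
  })
  structure(list(distances = distances, B = B, seed = seed,
                 source = paste(db$manifest$recording_id, collapse = ",")),
            class = "null_distribution")
}

#' Percentile of an observed distance within a null distribution
#'
#' Midrank convention: `100 * (#\{null < obs\} + 0.5 * #\{null = obs\}) / B`.
#' Percentiles near 0 mean the observed comparison is more similar than
#' almost all random pairings; near 100, less similar.
#'
#' @param observed observed DTW distance.
#' @param null a `null_distribution` or numeric vector.
#' @return Percentile in \[0, 100\].
#' @export
percentile_of <- function(observed, null) {
  d <- if (inherits(null, "null_distribution")) null$distances
       else as.numeric(null)
  assert_that(length(d) > 0, "nmmap_validation_error",
              "null distribution is empty")
  100 * (sum(d < observed) + 0.5 * sum(d == observed)) / length(d)
}

#' Classify a similarity percentile
#'
#' `quant_plus` iff the percentile is strictly below the threshold
#' (default 5); a value exactly at the threshold is `quant_minus`.
#'
#' @param percentile value in \[0, 100\].
#' @param threshold classification threshold (default 5).
#' @return `"quant_plus"` or `"quant_minus"`.
#' @export
classify_percentile <- function(percentile, threshold = 5) {
  assert_that(all(percentile >= 0 & percentile <= 100),
              "nmmap_validation_error", "percentile must lie in [0, 100]")
  ifelse(percentile < threshold, "quant_plus", "quant_minus")
}
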