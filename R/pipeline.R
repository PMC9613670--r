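#' Run configuration
#'
#' Bundles every tunable pipeline parameter with defaults; fully
#' serializable, so a run's JSON sidecar reproduces it bit-exact.
#'
#' @param seed master seed; per-epoch substreams are derived from it, so
#'   epoch processing order never changes any epoch's result.
#' @param window_s DTW band half-width, seconds.
#' @param B null-distribution size.
#' @param threshold_pct quant+/- classification threshold.
#' @param smoothing_window_s kinematic smoothing window, seconds.
#' @param artifact_sd kinematic artifact threshold, SDs.
#' @param likelihood_min tracking likelihood gate.
#' @param fingertip_landmarks landmark names averaged into the kinematic
#'   signal.
#' @param fs_common common analysis rate, Hz.
#' @param band_hz,filter_order,start_k,k_range,rate_bounds_hz,k_step,polarity
#'   MUA parameters, see [bandpass_mua()] and [detect_spikes_adaptive()].
#' @param null_exclusion null eligibility policy, see [build_null()].
#' @param max_flagged_fraction epochs with a larger flagged fraction are
#'   excluded as unusable.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, window_s = 0.2, B = 1000,
                       threshold_pct = 5, smoothing_window_s = 0.333,
                       artifact_sd = 4.5, likelihood_min = 0.6,
                       fingertip_landmarks = .fingertip_landmarks,
                       fs_common = 1200, band_hz = c(100, 4000),
                       filter_order = 2, start_k = 4.5,
                       k_range = c(2.5, 6.5), rate_bounds_hz = c(80, 400),
                       k_step = 0.1, polarity = "absolute",
                       null_exclusion = "own_window",
                       max_flagged_fraction = 0.5) {
  structure(list(seed = as.integer(seed), window_s = window_s, B = B,
                 threshold_pct = threshold_pct,
                 smoothing_window_s = smoothing_window_s,
                 artifact_sd = artifact_sd, likelihood_min = likelihood_min,
                 fingertip_landmarks = fingertip_landmarks,
                 fs_common = fs_common, band_hz = band_hz,
                 filter_order = filter_order, start_k = start_k,
                 k_range = k_range, rate_bounds_hz = rate_bounds_hz,
                 k_step = k_step, polarity = polarity,
                 null_exclusion = null_exclusion,
                 max_flagged_fraction = max_flagged_fraction),
            class = "run_config")
}

#' Full kinematic processing path
#'
#' Fingertip displacement, artifact repair (per landmark, before
#' averaging), fingertip averaging with smoothing, anti-aliased resampling
#' to the common rate, min-max normalization.
#'
#' @param track a [keypoint_table()].
#' @param landmarks landmarks to average (default: the five fingertips).
#' @param likelihood_min,artifact_sd,smoothing_window_s,fs_out parameters,
#'   see the stage functions.
#' @return A normalized [kinematic_signal()] with a QC attribute
#'   (`n_flagged`, `pct_flagged`, `landmarks_used`).
#' @export
process_kinematics <- function(track, landmarks = .fingertip_landmarks,
                               likelihood_min = 0.6, artifact_sd = 4.5,
                               smoothing_window_s = 0.333, fs_out = 1200) {
  landmarks <- intersect(landmarks, track$landmarks)
  assert_that(length(landmarks) >= 1, "nmmap_validation_error",
              "none of the requested landmarks are present")
  repaired <- lapply(landmarks, function(lm)
    repair_artifacts(frame_displacement(track, lm, likelihood_min),
                     k_sd = artifact_sd))
  n_flagged <- sum(vapply(repaired, function(s) sum(s$flags), 0L))
  n_total <- sum(vapply(repaired, function(s) length(s$values), 0L))
  agg <- aggregate_fingertips(repaired, smoothing_window_s)
  out <- normalize_01(resample_to_common(agg, fs_out))
  attr(out, "qc") <- list(n_flagged = n_flagged,
                          pct_flagged = 100 * n_flagged / n_total,
                          landmarks_used = landmarks)
  out
}

#' Process one epoch end to end
#'
#' Runs the kinematic and MUA paths independently, trims both 1200 Hz
#' signals to their common length, and computes the DTW similarity,
#' bootstrap null, percentile, and quant label. Quality failures (excessive
#' occlusion, constant signals) mark the epoch as excluded instead of
#' aborting; the returned stub records the reason.
#'
#' @param epoch an [epoch_record()].
#' @param db a [mua_segment_db()].
#' @param cfg a [run_config()]; the epoch's null seed is derived from
#'   `cfg$seed` and the epoch id.
#' @return An `nm_similarity` object, or an excluded stub (class
#'   `nm_similarity`, `excluded = TRUE`, `NA` percentile).
#' @export
run_epoch <- function(epoch, db, cfg = run_config()) {
  stopifnot(inherits(epoch, "epoch_record"))
  excluded <- function(reason) {
    structure(list(epoch_id = epoch$epoch_id,
                   movement_type = epoch$movement_type,
                   clinician_label = epoch$clinician_label,
                   dtw_distance = NA_real_, percentile = NA_real_,
                   quant_label = NA_character_, excluded = TRUE,
                   reason = reason, null = NULL),
              class = "nm_similarity")
  }
  kin <- tryCatch(
    process_kinematics(epoch$kinematics,
                       landmarks = cfg$fingertip_landmarks,
                       likelihood_min = cfg$likelihood_min,
                       artifact_sd = cfg$artifact_sd,
                       smoothing_window_s = cfg$smoothing_window_s,
                       fs_out = cfg$fs_common),
    nmmap_quality_error = function(e) e, nmmap_degenerate_error = function(e) e)
  if (inherits(kin, "condition"))
    return(excluded(conditionMessage(kin)))
  rate <- tryCatch(
    process_mua(epoch$voltage, n_samples = length(kin$values),
                fs_out = cfg$fs_common, band_hz = cfg$band_hz,
                order = cfg$filter_order, start_k = cfg$start_k,
                k_range = cfg$k_range, rate_bounds_hz = cfg$rate_bounds_hz,
                step = cfg$k_step, polarity = cfg$polarity),
    nmmap_degenerate_error = function(e) e)
  if (inherits(rate, "condition"))
    return(excluded(conditionMessage(rate)))
  if (rate$stage != "normalized")
    return(excluded("constant firing-rate signal (fewer than 2 spikes)"))
  nm_similarity(kin, rate, db,
                window_s = cfg$window_s, B = cfg$B,
                seed = derive_seed(cfg$seed, epoch$epoch_id),
                threshold = cfg$threshold_pct,
                epoch_id = epoch$epoch_id,
                movement_type = epoch$movement_type,
                clinician_label = epoch$clinician_label,
                policy = cfg$null_exclusion, fs = cfg$fs_common)
}

#' Run a full session
#'
#' Maps [run_epoch()] over all epochs, writes the results CSV and JSON
#' sidecar (package version, configuration, per-epoch null distributions),
#' and — when both clinician labels are present for a movement type — the
#' group-level evaluation report.
#'
#' @param epochs list of [epoch_record()]s.
#' @param db a [mua_segment_db()].
#' @param cfg a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param n_shuffle,n_boot evaluation parameters.
#' @return List: `results` (per-epoch `nm_similarity`), `table`
#'   (data.frame), `evaluation` (`nm_evaluation` or `NULL`).
#' @export
run_session <- function(epochs, db, cfg = run_config(), out_dir = NULL,
                        n_shuffle = 1000, n_boot = 1000) {
  assert_that(length(epochs) > 0, "nmmap_run_error", "no epochs to process")
  results <- lapply(epochs, run_epoch, db = db, cfg = cfg)
  usable <- !vapply(results, function(r) isTRUE(r$excluded), TRUE)
  assert_that(any(usable), "nmmap_run_error", "zero usable epochs")
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(epoch_id = r$epoch_id, movement_type = r$movement_type,
               clinician_label = r$clinician_label,
               dtw_distance = r$dtw_distance, percentile = r$percentile,
               quant_label = r$quant_label, excluded = isTRUE(r$excluded),
               stringsAsFactors = FALSE)))
  ev <- tryCatch(
    nm_evaluate(tab[!tab$excluded, ], n_shuffle = n_shuffle,
                n_boot = n_boot, seed = cfg$seed),
    nmmap_validation_error = function(e) NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
    write_results(results, file.path(out_dir, "results.csv"),
                  config = c(unclass(cfg),
                             list(config_sha1 = .config_hash(cfg_json))))
    if (!is.null(ev))
      jsonlite::write_json(.evaluation_report(ev),
                           file.path(out_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  list(results = results, table = tab, evaluation = ev)
}

.config_hash <- function(json) {
  # small stable fingerprint of the serialized config (polynomial hash)
  sprintf("%08x", derive_seed(7919L, as.character(json)))
}

.evaluation_report <- function(ev) {
  lapply(unclass(ev), function(e) {
    list(n = e$n,
         comparison = e$comparison,
         shift = if (!is.null(e$shift)) as.list(e$shift) else NULL,
         thresholds = if (!is.null(e$thresholds)) {
           t <- e$thresholds
           list(best_threshold = t$best_threshold,
                max_difference = t$max_difference,
                rate_plus = t$rate_plus, rate_minus = t$rate_minus,
                odds_ratio = t$odds_ratio, fisher_p = t$fisher_p,
                table_at_best = as.vector(t$table_at_best))
         } else NULL)
  })
}
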