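#' Motor-testing epoch records
#'
#' An `epoch_record` binds one motor-testing epoch's kinematics (a
#' [keypoint_table()] slice), its microelectrode voltage (a [voltage_trace()]
#' slice), the movement type (`active` = patient-driven, `passive` =
#' clinician-driven), the clinician's case-note label (`clin_plus`,
#' `clin_minus`, or `unclear`), and the video-to-neural clock offset.
#' The two slices must cover the same wall-clock interval once `t_offset_s`
#' is applied; stream synchronization itself is the recording system's job
#' and is taken as given.
#'
#' @param epoch_id character identifier.
#' @param movement_type `"active"` or `"passive"`.
#' @param clinician_label `"clin_plus"`, `"clin_minus"`, or `"unclear"`.
#' @param kinematics [keypoint_table()] covering the epoch.
#' @param voltage [voltage_trace()] covering the epoch.
#' @param t_offset_s video-to-neural alignment offset in seconds (neural
#'   time = video time + `t_offset_s`); default 0.
#' @return An `epoch_record`.
#' @export
epoch_record <- function(epoch_id, movement_type, clinician_label,
                         kinematics, voltage, t_offset_s = 0) {
  assert_that(movement_type %in% .movement_levels, "nmmap_validation_error",
              "movement_type must be one of: %s",
              paste(.movement_levels, collapse = ", "))
  assert_that(clinician_label %in% .clin_levels, "nmmap_validation_error",
              "clinician_label must be one of: %s",
              paste(.clin_levels, collapse = ", "))
  stopifnot(inherits(kinematics, "keypoint_table"),
            inherits(voltage, "voltage_trace"))
  dur_video <- kinematics$n_frames / kinematics$frame_rate
  assert_that(abs(dur_video - voltage$duration_s) <= 1 / kinematics$frame_rate,
              "nmmap_validation_error",
              "epoch %s: kinematic (%.3f s) and voltage (%.3f s) slices must cover the same interval",
              epoch_id, dur_video, voltage$duration_s)
  structure(list(epoch_id = as.character(epoch_id),
                 movement_type = movement_type,
                 clinician_label = clinician_label,
                 kinematics = kinematics, voltage = voltage,
                 t_offset_s = t_offset_s),
            class = "epoch_record")
}

#' @export
print.epoch_record <- function(x, ...) {
  cat(sprintf("<epoch_record> %s: %s, %s, %.1f s\n", x$epoch_id,
              x$movement_type, x$clinician_label, x$voltage$duration_s))
  invisible(x)
}

#' Read epoch metadata
#'
#' Epoch metadata is a YAML list of records with fields `epoch_id`,
#' `movement_type`, `clinician_label`, `video_start_s`, `video_end_s`,
#' `neural_start_s`, `neural_end_s`, and optional `t_offset_s` (default 0).
#'
#' @param path YAML file.
#' @return A data.frame with one row per epoch.
#' @export
read_epoch_metadata <- function(path) {
  assert_that(file.exists(path), "nmmap_io_error", "file not found: %s", path)
  raw <- yaml::read_yaml(path)
  assert_that(length(raw) > 0, "nmmap_validation_error",
              "epoch metadata is empty")
  need <- c("epoch_id", "movement_type", "clinician_label",
            "video_start_s", "video_end_s", "neural_start_s", "neural_end_s")
  rows <- lapply(raw, function(r) {
    miss <- setdiff(need, names(r))
    assert_that(length(miss) == 0, "nmmap_format_error",
                "epoch metadata record missing field(s): %s",
                paste(miss, collapse = ", "))
    if (is.null(r$t_offset_s)) r$t_offset_s <- 0
    as.data.frame(r[c(need, "t_offset_s")], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write epoch metadata
#'
#' @param meta data.frame as returned by [read_epoch_metadata()].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_epoch_metadata <- function(meta, path) {
  recs <- lapply(seq_len(nrow(meta)), function(i) as.list(meta[i, ]))
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Cut an epoch out of full-session recordings
#'
#' Slices are half-open on time: a sample or frame at exactly the epoch end
#' belongs to the next epoch. Frame/sample indices are 0-based.
#'
#' @param meta_row one row of the epoch metadata data.frame.
#' @param track full-session [keypoint_table()].
#' @param trace full-session [voltage_trace()].
#' @return An [epoch_record()].
#' @export
slice_epoch <- function(meta_row, track, trace) {
  fr <- track$frame_rate
  f0 <- floor(meta_row$video_start_s * fr + 1e-9)
  f1 <- floor(meta_row$video_end_s * fr - 1e-9)       # last frame < end
  assert_that(f1 >= f0 && f1 < track$n_frames, "nmmap_validation_error",
              "epoch %s: video interval outside recording", meta_row$epoch_id)
  idx <- (f0:f1) + 1L
  kt <- keypoint_table(track$x[idx, , drop = FALSE],
                       track$y[idx, , drop = FALSE],
                       track$likelihood[idx, , drop = FALSE], fr)
  s0 <- floor(meta_row$neural_start_s * trace$fs + 1e-9)
  s1 <- floor(meta_row$neural_end_s * trace$fs - 1e-9)
  assert_that(s1 >= s0 && s1 < length(trace$samples),
              "nmmap_validation_error",
              "epoch %s: neural interval outside recording", meta_row$epoch_id)
  vt <- voltage_trace(trace$samples[(s0:s1) + 1L], trace$fs)
  epoch_record(meta_row$epoch_id, meta_row$movement_type,
               meta_row$clinician_label, kt, vt,
               t_offset_s = meta_row$t_offset_s)
}

#' Write similarity results
#'
#' Writes one CSV row per epoch (`epoch_id, movement_type, clinician_label,
#' dtw_distance, percentile, quant_label`) plus a JSON sidecar (same path
#' with `.json` appended) carrying each epoch's full null distribution and
#' the run configuration, so a run can be audited and reproduced.
#'
#' @param results non-empty list of `nm_similarity` objects.
#' @param path output CSV path.
#' @param config optional named list of run parameters stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = list()) {
  assert_that(length(results) > 0, "nmmap_validation_error",
              "results list is empty")
  rows <- lapply(results, function(r) {
    data.frame(epoch_id = r$epoch_id,
               movement_type = r$movement_type %||% NA_character_,
               clinician_label = r$clinician_label %||% NA_character_,
               dtw_distance = r$dtw_distance,
               percentile = r$percentile,
               quant_label = r$quant_label,
               excluded = isTRUE(r$excluded),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(tab, path, row.names = FALSE)
  sidecar <- list(
    package_version = as.character(utils::packageVersion("nmmap")),
    config = config,
    nulls = lapply(results, function(r)
      list(epoch_id = r$epoch_id,
           seed = r$null$seed %||% NA,
           distances = r$null$distances %||% numeric(0))))
  # digits = I(17): significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Read back a results CSV and its JSON sidecar
#'
#' @param path the CSV path given to [write_results()].
#' @return A list with `table` (data.frame) and `sidecar` (parsed JSON).
#' @export
read_results <- function(path) {
  list(table = read.csv(path, stringsAsFactors = FALSE),
       sidecar = jsonlite::read_json(paste0(path, ".json"),
                                     simplifyVector = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
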