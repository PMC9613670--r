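#' Keypoint tables
#'
#' A `keypoint_table` holds per-frame markerless-tracking output for a set of
#' anatomical hand landmarks: x/y pixel coordinates (image convention: origin
#' top-left, y increasing downward) and a tracking likelihood in \[0, 1\].
#' Missing detections are explicit `NA`s, never zeros. Frame indices are
#' 0-based and time intervals are half-open `[start, end)`.
#'
#' @param x,y,likelihood numeric matrices, one row per frame and one column
#'   per landmark (column names are the landmark names).
#' @param frame_rate frames per second (60 for the supported cameras).
#' @return A `keypoint_table`.
#' @export
keypoint_table <- function(x, y, likelihood, frame_rate = 60) {
  assert_that(is.matrix(x) && is.matrix(y) && is.matrix(likelihood),
              "nmmap_validation_error", "x, y, likelihood must be matrices")
  assert_that(all(dim(x) == dim(y)) && all(dim(x) == dim(likelihood)),
              "nmmap_validation_error",
              "every landmark must have exactly n_frames records")
  assert_that(!is.null(colnames(x)), "nmmap_validation_error",
              "landmark names are required as column names")
  assert_that(is_scalar_number(frame_rate) && frame_rate > 0,
              "nmmap_validation_error", "frame_rate must be positive")
  lk <- likelihood[!is.na(likelihood)]
  assert_that(all(lk >= 0 & lk <= 1), "nmmap_validation_error",
              "likelihood values must lie in [0, 1]")
  structure(list(x = x, y = y, likelihood = likelihood,
                 frame_rate = frame_rate,
                 landmarks = colnames(x), n_frames = nrow(x)),
            class = "keypoint_table")
}

#' @export
print.keypoint_table <- function(x, ...) {
  cat(sprintf("<keypoint_table> %d frames @ %g Hz, %d landmarks\n",
              x$n_frames, x$frame_rate, length(x$landmarks)))
  invisible(x)
}

#' Read a markerless-tracking keypoint table
#'
#' Supports the DeepLabCut-style CSV dialect (three header rows:
#' scorer / bodyparts / coords, with x, y, likelihood triplets per landmark)
#' and a plain long-format TSV (`frame, landmark, x, y, likelihood`; a
#' missing likelihood column is imputed as 1.0). Empty cells become `NA`.
#'
#' @param path path to the table.
#' @param dialect one of `"dlc_csv"`, `"plain_tsv"`, `"dlc_hdf"`. The HDF
#'   dialect is not available in this build (no R HDF5 reader is bundled)
#'   and raises an error directing users to the CSV export.
#' @param frame_rate frames per second of the source video.
#' @param min_landmarks minimum number of landmarks required (the pipeline
#'   needs at least the five fingertips).
#' @return A [keypoint_table()].
#' @export
read_keypoint_table <- function(path, dialect = c("dlc_csv", "plain_tsv",
                                                  "dlc_hdf"),
                                frame_rate = 60, min_landmarks = 5) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "nmmap_io_error", "file not found: %s", path)
  if (dialect == "dlc_hdf")
    stop_nmmap("nmmap_format_error",
               "dlc_hdf is not supported in this build; export the table as CSV")
  tab <- if (dialect == "dlc_csv") .read_dlc_csv(path, frame_rate)
         else .read_plain_tsv(path, frame_rate)
  assert_that(length(tab$landmarks) >= min_landmarks,
              "nmmap_validation_error",
              "only %d landmarks present; at least %d (the fingertips) required",
              length(tab$landmarks), min_landmarks)
  tab
}

.read_dlc_csv <- function(path, frame_rate) {
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3)
    stop_nmmap("nmmap_format_error",
               "malformed DLC header: expected 3 header rows, got %d",
               length(hdr))
  split1 <- strsplit(hdr, ",", fixed = TRUE)
  labels <- vapply(split1, `[[`, "", 1)
  if (!identical(tolower(labels), c("scorer", "bodyparts", "coords")))
    stop_nmmap("nmmap_format_error",
               "malformed DLC header at line %d: expected scorer/bodyparts/coords, got '%s'",
               which(tolower(labels) != c("scorer", "bodyparts", "coords"))[1],
               labels[tolower(labels) != c("scorer", "bodyparts", "coords")][1])
  bodyparts <- split1[[2]][-1]
  coords <- split1[[3]][-1]
  if (length(bodyparts) != length(coords) || length(bodyparts) %% 3 != 0)
    stop_nmmap("nmmap_format_error",
               "malformed DLC header at line 3: expected x,y,likelihood triplets")
  dat <- read.csv(path, skip = 3, header = FALSE, na.strings = c("", "NA"))
  if (ncol(dat) != length(bodyparts) + 1)
    stop_nmmap("nmmap_format_error",
               "data rows have %d columns but header declares %d",
               ncol(dat), length(bodyparts) + 1)
  landmarks <- unique(bodyparts)
  n <- nrow(dat)
  get_col <- function(lm, what) {
    j <- which(bodyparts == lm & coords == what)
    if (length(j) != 1)
      stop_nmmap("nmmap_format_error",
                 "landmark '%s' lacks a '%s' column", lm, what)
    as.numeric(dat[[j + 1]])
  }
  x <- sapply(landmarks, get_col, "x")
  y <- sapply(landmarks, get_col, "y")
  lk <- sapply(landmarks, get_col, "likelihood")
  dim(x) <- dim(y) <- dim(lk) <- c(n, length(landmarks))
  colnames(x) <- colnames(y) <- colnames(lk) <- landmarks
  keypoint_table(x, y, lk, frame_rate)
}

.read_plain_tsv <- function(path, frame_rate) {
  dat <- read.csv(path, sep = "\t", header = TRUE, na.strings = c("", "NA"))
  need <- c("frame", "landmark", "x", "y")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop_nmmap("nmmap_format_error",
               "malformed plain_tsv header: missing column(s) %s",
               paste(miss, collapse = ", "))
  if (is.null(dat$likelihood)) dat$likelihood <- 1.0  # documented default
  landmarks <- unique(as.character(dat$landmark))
  frames <- sort(unique(dat$frame))
  n <- length(frames)
  x <- y <- lk <- matrix(NA_real_, n, length(landmarks),
                         dimnames = list(NULL, landmarks))
  ri <- match(dat$frame, frames)
  ci <- match(as.character(dat$landmark), landmarks)
  x[cbind(ri, ci)] <- dat$x
  y[cbind(ri, ci)] <- dat$y
  lk[cbind(ri, ci)] <- dat$likelihood
  keypoint_table(x, y, lk, frame_rate)
}

#' Write a keypoint table
#'
#' Inverse of [read_keypoint_table()] for the two text dialects; round-trips
#' are lossless up to numeric formatting (15 significant digits).
#'
#' @param tab a [keypoint_table()].
#' @param path output path.
#' @param dialect `"dlc_csv"` or `"plain_tsv"`.
#' @return `path`, invisibly.
#' @export
write_keypoint_table <- function(tab, path,
                                 dialect = c("dlc_csv", "plain_tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(tab, "keypoint_table"))
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 15,
                                                  format = "g"))
  if (dialect == "dlc_csv") {
    lms <- tab$landmarks
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("scorer",
                       rep("nmmap", 3 * length(lms))), collapse = ","), con)
    writeLines(paste(c("bodyparts", rep(lms, each = 3)), collapse = ","), con)
    writeLines(paste(c("coords",
                       rep(c("x", "y", "likelihood"), length(lms))),
                     collapse = ","), con)
    body <- matrix("", tab$n_frames, 1 + 3 * length(lms))
    body[, 1] <- as.character(seq_len(tab$n_frames) - 1L)
    for (j in seq_along(lms)) {
      body[, 3 * j - 1] <- fmt(tab$x[, j])
      body[, 3 * j]     <- fmt(tab$y[, j])
      body[, 3 * j + 1] <- fmt(tab$likelihood[, j])
    }
    writeLines(apply(body, 1, paste, collapse = ","), con)
  } else {
    long <- data.frame(
      frame = rep(seq_len(tab$n_frames) - 1L, times = length(tab$landmarks)),
      landmark = rep(tab$landmarks, each = tab$n_frames),
      x = as.vector(tab$x), y = as.vector(tab$y),
      likelihood = as.vector(tab$likelihood))
    write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE,
                na = "")
  }
  invisible(path)
}
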