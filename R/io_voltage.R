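#' Read a single-channel voltage trace
#'
#' Accepts RIFF WAV (PCM16 or IEEE float32; the sampling rate comes from the
#' header) or a single-column CSV (the rate must be supplied via `fs_hint`).
#' HDF5 input is not available in this build and raises an error. No
#' resampling is performed here.
#'
#' @param path input file (`.wav` or `.csv`).
#' @param fs_hint sampling rate in Hz when the container carries none;
#'   overrides nothing when the container declares a rate.
#' @return A [voltage_trace()].
#' @export
read_voltage <- function(path, fs_hint = NULL) {
  assert_that(file.exists(path), "nmmap_io_error", "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5", "hdf"))
    stop_nmmap("nmmap_format_error",
               "HDF5 voltage input is not supported in this build; use WAV or CSV")
  if (ext == "wav") {
    wav <- .read_wav(path)
    return(voltage_trace(wav$samples, wav$fs))
  }
  # CSV path: one sample per line, optional header "voltage"
  assert_that(!is.null(fs_hint), "nmmap_config_error",
              "sampling rate unavailable: CSV input requires fs_hint")
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(first)))
  v <- read.csv(path, header = has_header)[[1]]
  voltage_trace(as.numeric(v), fs_hint)
}

#' Write a voltage trace
#'
#' @param trace a [voltage_trace()].
#' @param path output path; `.wav` writes IEEE float32 WAV (lossless for the
#'   values the pipeline produces), `.csv` a one-column CSV.
#' @return `path`, invisibly.
#' @export
write_voltage <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "wav") {
    .write_wav_float32(trace$samples, trace$fs, path)
  } else {
    write.csv(data.frame(voltage = trace$samples), path, row.names = FALSE)
  }
  invisible(path)
}

# --- minimal RIFF/WAVE support (PCM16 and IEEE float32, mono or first
# channel of interleaved data). Written with readBin/writeBin because no
# audio package is bundled; covered by round-trip tests. ---

.read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop_nmmap("nmmap_format_error", "not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop_nmmap("nmmap_format_error", "not a WAVE file: %s", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2,
                             signed = FALSE, endian = "little"),
        fs = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop_nmmap("nmmap_format_error", "WAV missing fmt or data chunk: %s", path)
  if (fmt$audio_format == 1 && fmt$bits == 16) {
    v <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    v <- readBin(data_raw, "double", length(data_raw) / 4, 4,
                 endian = "little")
  } else {
    stop_nmmap("nmmap_format_error",
               "unsupported WAV encoding (format %d, %d bits)",
               fmt$audio_format, fmt$bits)
  }
  if (fmt$n_channels > 1)
    v <- v[seq(1, length(v), by = fmt$n_channels)]
  list(samples = v, fs = fmt$fs)
}

.write_wav_float32 <- function(samples, fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(samples) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(3L, con, 2, endian = "little")          # IEEE float
  writeBin(1L, con, 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 4), con, 4, endian = "little")  # byte rate
  writeBin(4L, con, 2, endian = "little")          # block align
  writeBin(32L, con, 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(samples, con, 4, endian = "little")
  invisible(path)
}
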