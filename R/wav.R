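#' Read a PCM WAV file
#'
#' Reads an uncompressed RIFF/WAVE file (PCM, 8/16/24/32-bit integer or
#' 32/64-bit IEEE float). Multi-channel input is averaged to a single mono
#' channel; samples are returned on a normalized scale in \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @param species_id,recording_id Optional identifiers attached to the
#'   returned object (default: the file name for `recording_id`).
#' @return A `recording` object: a list with elements `samples` (numeric
#'   vector), `sample_rate` (Hz), `species_id` and `recording_id`.
#' @export
read_wav <- function(path, species_id = NA_character_,
                     recording_id = basename(path)) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF/WAVE file (missing RIFF header): ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4,
                               endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE,
                               endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("malformed WAV (no fmt chunk): ", path)
  if (is.null(data_raw) || length(data_raw) == 0)
    stop("empty WAV data chunk: ", path)
  # 1 = integer PCM, 3 = IEEE float; anything else is a compressed codec
  if (!fmt$audio_format %in% c(1L, 3L))
    stop("unsupported WAV codec (format tag ", fmt$audio_format,
         "); only PCM and IEEE float are readable: ", path)

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 3L) {
    readBin(data_raw, "double", n_total, size = bytes, endian = "little")
  } else if (fmt$bits == 8L) {
    # 8-bit PCM is unsigned, midpoint 128
    (readBin(data_raw, "integer", n_total, size = 1, signed = FALSE) - 128) / 128
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3L)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else {
    readBin(data_raw, "integer", n_total, size = bytes, signed = TRUE,
            endian = "little") / 2^(fmt$bits - 1)
  }
  if (fmt$n_channels > 1L) {
    n_frames <- length(x) %/% fmt$n_channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$n_channels)],
                         nrow = fmt$n_channels))
  }
  recording(x, fmt$sample_rate, species_id = species_id,
            recording_id = recording_id)
}

#' Construct a recording object
#'
#' @param samples Numeric amplitude vector, nominally in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @param species_id,recording_id Identifiers.
#' @return A `recording` object.
#' @export
recording <- function(samples, sample_rate, species_id = NA_character_,
                      recording_id = NA_character_) {
  stopifnot(is.numeric(samples), length(samples) > 0,
            is.numeric(sample_rate), sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 species_id = species_id, recording_id = recording_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s> %.3f s at %g Hz (%d samples)\n",
              x$recording_id, length(x$samples) / x$sample_rate,
              x$sample_rate, length(x$samples)))
  invisible(x)
}

#' Write a recording to a 16-bit PCM WAV file
#'
#' @param rec A `recording` object (samples are clipped to \[-1, 1\]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  x <- pmax(pmin(rec$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little")   # PCM, mono
  writeBin(as.integer(rec$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(c(2, 16)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
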