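#' Recording container
#'
#' A mono recording: float samples nominally in `[-1, 1]` plus a sample rate.
#' Multi-channel audio is reduced to one channel before storage.
#'
#' @param samples numeric vector of amplitudes.
#' @param rate_hz sample rate in Hz (`> 0`).
#' @param source_name label for provenance (file name or "synthetic").
#' @return An object of class `usv_recording` with fields `samples`,
#'   `rate_hz`, `source_name`.
#' @export
usv_recording <- function(samples, rate_hz, source_name = "unknown") {
  if (length(samples) < 1L) stop("empty audio: a recording needs at least one sample")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  structure(list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
                 source_name = as.character(source_name)),
            class = "usv_recording")
}

#' @export
print.usv_recording <- function(x, ...) {
  cat(sprintf("<usv_recording> %s: %d samples @ %g Hz (%.3f s)\n",
              x$source_name, length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz))
  invisible(x)
}

#' Read a WAV file
#'
#' Reads RIFF/WAVE audio: PCM 16/24/32-bit integer or IEEE float 32/64-bit,
#' mono or multi-channel. Integer samples are scaled to `[-1, 1]` by the
#' full-scale value of the bit depth. Compressed formats are rejected.
#'
#' @param path path to a WAV file.
#' @param channel_policy `"first"` keeps channel 1; `"mean"` averages
#'   channels per frame.
#' @return A [usv_recording()].
#' @export
read_wav <- function(path, channel_policy = c("first", "mean")) {
  channel_policy <- match.arg(channel_policy)
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id, type = "bytes") < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little"))
      if (fmt$format == 65534L && size >= 26L) # WAVE_FORMAT_EXTENSIBLE
        fmt$format <- readBin(raw[25:26], "integer", 1L, 2L, signed = FALSE, endian = "little")
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("malformed WAV: no fmt chunk in ", path)
  if (is.null(data_raw) || length(data_raw) == 0L) stop("empty audio in ", path)
  x <- decode_wav_samples(data_raw, fmt)
  if (fmt$n_channels > 1L) {
    m <- matrix(x, nrow = fmt$n_channels)
    x <- if (channel_policy == "first") m[1L, ] else colMeans(m)
  }
  if (length(x) == 0L) stop("empty audio in ", path)
  usv_recording(x, fmt$rate, basename(path))
}

decode_wav_samples <- function(raw, fmt) {
  n_bytes <- fmt$bits %/% 8L
  n <- length(raw) %/% n_bytes
  if (fmt$format == 1L) { # integer PCM
    if (fmt$bits == 16L) {
      readBin(raw, "integer", n, 2L, signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      b <- as.integer(raw[seq_len(n * 3L)])
      dim(b) <- c(3L, n)
      v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(raw, "integer", n, 4L, endian = "little") / 2147483648
    } else if (fmt$bits == 8L) {
      (readBin(raw, "integer", n, 1L, signed = FALSE) - 128) / 128
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$format == 3L) { # IEEE float
    if (fmt$bits == 32L) {
      readBin(raw, "numeric", n, 4L, endian = "little")
    } else if (fmt$bits == 64L) {
      readBin(raw, "numeric", n, 8L, endian = "little")
    } else stop("unsupported float bit depth: ", fmt$bits)
  } else {
    stop("unsupported/compressed WAV format code: ", fmt$format)
  }
}

#' Write a WAV file
#'
#' @param rec a [usv_recording()].
#' @param path output path.
#' @param format `"float32"` (exact for synthetic fixtures) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- rec$samples
  rate <- as.integer(round(rec$rate_hz))
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (format == "float32") 32L else 16L
  fmt_code <- if (format == "float32") 3L else 1L
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(fmt_code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little") # mono
  writeBin(rate, con, 4L, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, 2L, endian = "little")
  writeBin(bits, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (format == "float32") {
    writeBin(x, con, 4L, endian = "little")
  } else {
    v <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(v, con, 2L, endian = "little")
  }
  invisible(path)
}
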