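#' Write a waveform to a PCM WAV file
#'
#' Writes a canonical RIFF/WAVE file with a 16-byte PCM `fmt ` chunk followed
#' by the `data` chunk: 16-bit signed little-endian samples, mono by default,
#' or two identical channels with `stereo = TRUE` (diotic presentation).
#' Samples are expected in `[-1, 1]` and are quantised by rounding to
#' `x * (2^15 - 1)`.
#'
#' @param waveform Numeric samples in `[-1, 1]`; must be non-empty.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz; defaults to the waveform's
#'   `sample_rate` attribute.
#' @param bit_depth PCM bit depth; only 16 is supported.
#' @param stereo Duplicate the mono signal into two channels.
#'
#' @return `path`, invisibly.
#'
#' @seealso [read_wav()]
#' @export
write_wav <- function(waveform, path,
                      sample_rate = attr(waveform, "sample_rate"),
                      bit_depth = 16L, stereo = FALSE) {
  if (length(waveform) == 0L) {
    abort("Refusing to write an empty waveform.",
          class = "pitchshift_invalid_parameter")
  }
  if (is.null(sample_rate)) {
    abort("`sample_rate` is required (no attribute found on the waveform).",
          class = "pitchshift_invalid_parameter")
  }
  if (bit_depth != 16L) {
    abort("Only 16-bit PCM output is supported.",
          class = "pitchshift_invalid_parameter")
  }
  if (max(abs(waveform)) > 1 + 1e-12) {
    abort("Samples must lie in [-1, 1].",
          class = "pitchshift_invalid_parameter")
  }
  n_channels <- if (stereo) 2L else 1L
  q <- as.integer(round(pmin(pmax(waveform, -1), 1) * 32767))
  if (stereo) q <- rep(q, each = 2L)

  block_align <- n_channels * 2L
  byte_rate <- sample_rate * block_align
  data_bytes <- length(q) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")         # PCM fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")          # audio format: PCM
  writeBin(n_channels, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Parses the RIFF chunk list, accepting any chunk order, and returns the
#' samples rescaled to `[-1, 1]`. Only 16-bit PCM is supported. Stereo files
#' are returned with one column per channel.
#'
#' @param path WAV file path.
#'
#' @return A list with `samples` (numeric vector, or matrix with one column
#'   per channel), `sample_rate`, `bit_depth`, `n_channels`, `n_frames`.
#'
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("Not a RIFF/WAVE file: %s", path), class = "pitchshift_io_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", size = 2, endian = "little"),
        n_channels = readBin(con, "integer", size = 2, endian = "little"),
        sample_rate = readBin(con, "integer", size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", size = 4, endian = "little"),
        block_align = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little")
      )
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", n = size)
    } else {
      readBin(con, "raw", n = size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("Missing fmt/data chunk in %s", path),
          class = "pitchshift_io_error")
  }
  if (fmt$format != 1L || fmt$bits != 16L) {
    abort("Only 16-bit PCM WAV is supported.", class = "pitchshift_io_error")
  }
  vals <- readBin(data_raw, "integer", n = length(data_raw) / 2L,
                  size = 2, signed = TRUE, endian = "little") / 32767
  n_frames <- length(vals) %/% fmt$n_channels
  samples <- if (fmt$n_channels > 1L) {
    t(matrix(vals, nrow = fmt$n_channels))
  } else {
    vals
  }
  list(
    samples = samples,
    sample_rate = fmt$sample_rate,
    bit_depth = fmt$bits,
    n_channels = fmt$n_channels,
    n_frames = n_frames
  )
}
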