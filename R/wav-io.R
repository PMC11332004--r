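#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM audio (16- or 24-bit
#' integer, or 32-bit IEEE float). Stereo files are averaged to mono with a
#' warning; the SSS test records a single microphone channel.
#'
#' @param path Path to a `.wav` file.
#' @param participant_id Identifier attached to the returned signal; defaults
#'   to the file name without extension.
#' @return An [audio_signal] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path, participant_id = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("cannot read audio: file missing or empty: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = sum(as.integer(fmt_raw[1:2]) * c(1L, 256L)),
        channels  = sum(as.integer(fmt_raw[3:4]) * c(1L, 256L)),
        rate      = sum(as.integer(fmt_raw[5:8]) * 256^(0:3)),
        bits      = sum(as.integer(fmt_raw[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data): ", path)
  if (!fmt$format %in% c(1L, 3L)) stop("unsupported WAV encoding (need PCM or float)")

  x <- switch(
    as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) / 3
      b <- matrix(as.integer(data_raw), nrow = 3)
      v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$format == 3L) {
        readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
      } else {
        readBin(data_raw, "integer", length(data_raw) / 4, 4,
                endian = "little") / 2147483648
      }
    },
    stop("unsupported bit depth: ", fmt$bits)
  )

  if (fmt$channels > 1) {
    warning("multi-channel WAV averaged to mono (", fmt$channels, " channels)")
    nch <- fmt$channels
    usable <- nch * (length(x) %/% nch)
    x <- colMeans(matrix(x[seq_len(usable)], nrow = nch))
  }
  if (length(x) == 0) stop("cannot read audio: no samples in ", path)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  }
  audio_signal(x, fmt$rate, participant_id)
}

#' Write a mono signal as 16-bit PCM WAV
#'
#' @param x Numeric vector of samples; values are clipped to `[-1, 1]`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, sample_rate_hz, path) {
  stopifnot(is.numeric(x), length(x) > 0, sample_rate_hz > 0)
  x <- pmax(-1, pmin(1, x))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                     # PCM
  writeBin(1L, con, 2, endian = "little")                     # mono
  writeBin(as.integer(sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
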