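#' Audio signal container
#'
#' A mono audio signal with its sampling rate and a participant identifier.
#' Sampling rates must exceed 6 kHz so that the 3 kHz low-pass pre-filter is
#' realizable.
#'
#' @param samples Numeric vector of finite amplitudes (arbitrary units).
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param participant_id Identifier string.
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate_hz, participant_id = "unknown") {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate_hz > 0)
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = sample_rate_hz,
         participant_id = as.character(participant_id)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %s: %.2f s at %g Hz (%d samples)\n",
              x$participant_id, length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz, length(x$samples)))
  invisible(x)
}

#' Uniformly sampled amplitude envelope
#'
#' Container for a slow amplitude envelope: nonnegative before any band-pass
#' filtering (band-passed envelopes oscillate about zero and are flagged with
#' `bandpassed = TRUE`).
#'
#' @param values Numeric vector of finite amplitudes.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param source_id Identifier of the signal the envelope came from.
#' @param bandpassed Logical; has a band-pass filter been applied?
#' @return An object of class `envelope_series`.
#' @export
envelope_series <- function(values, sample_rate_hz, source_id = "unknown",
                            bandpassed = FALSE) {
  stopifnot(is.numeric(values), length(values) > 0, sample_rate_hz > 0)
  if (!all(is.finite(values))) stop("envelope values must be finite")
  if (!bandpassed && any(values < 0)) {
    stop("envelope values must be nonnegative before band-pass filtering")
  }
  structure(
    list(values = as.numeric(values),
         sample_rate_hz = sample_rate_hz,
         source_id = as.character(source_id),
         bandpassed = isTRUE(bandpassed)),
    class = "envelope_series"
  )
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %s: %.2f s at %g Hz%s\n",
              x$source_id, length(x$values) / x$sample_rate_hz,
              x$sample_rate_hz, if (x$bandpassed) " (band-passed)" else ""))
  invisible(x)
}

#' Duration of an envelope in seconds
#' @param env An [envelope_series].
#' @return Duration in seconds.
#' @export
envelope_duration <- function(env) length(env$values) / env$sample_rate_hz

#' Paired instantaneous phase series
#'
#' Houses the two phase series entering the phase-locking value: the phase of
#' the heard (stimulus) envelope and the phase of the produced envelope, on a
#' shared uniform time grid.
#'
#' @param theta1 Phase of the heard signal's envelope, radians.
#' @param theta2 Phase of the produced signal's envelope, radians.
#' @param sample_rate_hz Sampling rate of both series in Hz.
#' @return An object of class `phase_pair` with `T` shared time points.
#' @export
phase_pair <- function(theta1, theta2, sample_rate_hz) {
  stopifnot(is.numeric(theta1), is.numeric(theta2), sample_rate_hz > 0)
  if (length(theta1) != length(theta2)) {
    stop("phase series must have equal length")
  }
  if (!all(is.finite(theta1)) || !all(is.finite(theta2))) {
    stop("phases must be finite")
  }
  structure(
    list(theta1 = as.numeric(theta1), theta2 = as.numeric(theta2),
         T = length(theta1), sample_rate_hz = sample_rate_hz),
    class = "phase_pair"
  )
}

#' Write an envelope as a two-column CSV (time_s, amplitude)
#' @param env An [envelope_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(env, path) {
  t <- (seq_along(env$values) - 1) / env$sample_rate_hz
  utils::write.csv(data.frame(time_s = t, amplitude = env$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an envelope from a two-column CSV (time_s, amplitude)
#' @param path CSV path with columns `time_s` and `amplitude`.
#' @param source_id Identifier; defaults to file name.
#' @return An [envelope_series]; the rate is inferred from the time column.
#' @export
read_envelope_csv <- function(path, source_id = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(d))) {
    stop("envelope CSV needs columns time_s, amplitude: ", path)
  }
  if (nrow(d) < 2) stop("envelope CSV too short: ", path)
  dt <- diff(d$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("envelope CSV must be uniformly sampled: ", path)
  }
  if (is.null(source_id)) source_id <- sub("\\.csv$", "", basename(path))
  envelope_series(d$amplitude, 1 / mean(dt), source_id,
                  bandpassed = any(d$amplitude < 0))
}
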