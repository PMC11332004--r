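#' Low-pass pre-filter for recorded audio
#'
#' Applies the `[0, 3000]` Hz band (a 3 kHz low-pass) to stimulus and
#' produced signals to remove background noise before envelope extraction.
#' Realized as a 4th-order Butterworth applied forward-backward (zero phase),
#' preserving envelope timing.
#'
#' @param sig An [audio_signal] with `sample_rate_hz > 6000`.
#' @param cutoff_hz Low-pass cutoff in Hz (default 3000).
#' @return Filtered [audio_signal], same length and rate.
#' @export
prefilter <- function(sig, cutoff_hz = 3000) {
  stopifnot(inherits(sig, "audio_signal"))
  if (sig$sample_rate_hz <= 2 * cutoff_hz) {
    stop("sampling rate must exceed ", 2 * cutoff_hz,
         " Hz for the ", cutoff_hz, " Hz low-pass")
  }
  bf <- signal::butter(4, cutoff_hz / (sig$sample_rate_hz / 2), type = "low")
  audio_signal(signal::filtfilt(bf, sig$samples), sig$sample_rate_hz,
               sig$participant_id)
}

#' Quality control of a produced-speech recording
#'
#' Applies the inclusion criteria for the SSS test. Silence is detected on a
#' 50 ms moving-average envelope of the rectified signal: samples below
#' `silence_threshold` times the 95th-percentile amplitude count as silent,
#' and a participant is excluded when the longest silent run is strictly
#' longer than `max_silence_s` (default 4 s). Loud (non-whispered) speech and
#' background noise were excluded by experimenter judgment in the original
#' protocol; they are exposed here as manual flags, alongside the RMS level
#' that informs that judgment.
#'
#' @param sig An [audio_signal].
#' @param silence_threshold Fraction of the 95th-percentile amplitude below
#'   which a sample is silent (default 0.05). Relative thresholding makes the
#'   check invariant to global amplitude scaling.
#' @param max_silence_s Longest tolerated silence, seconds (default 4).
#' @param loud_speech,background_noise Manual review flags.
#' @return An object of class `qc_report`: `included`, `reasons`,
#'   `longest_silence_s`, `rms_level`, `participant_id`.
#' @export
quality_check <- function(sig, silence_threshold = 0.05, max_silence_s = 4,
                          loud_speech = FALSE, background_noise = FALSE) {
  stopifnot(inherits(sig, "audio_signal"))
  env <- smoothed_abs_envelope(sig$samples, sig$sample_rate_hz, 0.05)
  ref <- stats::quantile(env, 0.95, names = FALSE)
  silent <- if (ref > 0) env < silence_threshold * ref else rep(TRUE, length(env))
  longest <- longest_run(silent) / sig$sample_rate_hz

  reasons <- character(0)
  if (longest > max_silence_s) reasons <- c(reasons, "silence_gt_4s")
  if (isTRUE(loud_speech)) reasons <- c(reasons, "loud_speech")
  if (isTRUE(background_noise)) reasons <- c(reasons, "background_noise")

  structure(
    list(included = length(reasons) == 0,
         reasons = reasons,
         longest_silence_s = longest,
         rms_level = sqrt(mean(sig$samples^2)),
         participant_id = sig$participant_id),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s (longest silence %.2f s, RMS %.4g)\n",
              x$participant_id,
              if (x$included) "included" else
                paste("excluded:", paste(x$reasons, collapse = ", ")),
              x$longest_silence_s, x$rms_level))
  invisible(x)
}

# 50 ms (or win_s) moving-average of |x|; centered, edge-padded by filter().
smoothed_abs_envelope <- function(x, fs, win_s) {
  w <- max(1L, round(win_s * fs))
  k <- rep(1 / w, w)
  y <- stats::filter(abs(x), k, sides = 2)
  y[is.na(y)] <- abs(x)[is.na(y)]  # window edges: fall back to rectified value
  as.numeric(y)
}

longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' One-row data frame view of a QC report
#' @param report A `qc_report`.
#' @return A one-row `data.frame` suitable for `rbind`-ing across participants.
#' @export
qc_report_row <- function(report) {
  data.frame(
    participant_id = report$participant_id,
    included = report$included,
    reasons = paste(report$reasons, collapse = ";"),
    longest_silence_s = report$longest_silence_s,
    rms_level = report$rms_level,
    stringsAsFactors = FALSE
  )
}
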