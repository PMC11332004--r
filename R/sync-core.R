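#' Analytic signal via the Hilbert transform
#'
#' Computes the discrete analytic signal by zeroing negative frequencies of
#' the FFT (doubling positive ones), so that `Mod()` of the result is the
#' instantaneous amplitude and `Arg()` the instantaneous phase.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @keywords internal
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Extract the amplitude envelope of an audio signal
#'
#' The envelope is the modulus of the analytic (Hilbert-transformed) signal,
#' at the signal's native sampling rate. Apply [prefilter()] first for
#' recorded audio.
#'
#' @param sig An [audio_signal].
#' @return An [envelope_series] at the original rate.
#' @export
extract_envelope <- function(sig) {
  stopifnot(inherits(sig, "audio_signal"))
  env <- Mod(hilbert_analytic(sig$samples))
  envelope_series(env, sig$sample_rate_hz, sig$participant_id)
}

#' Resample an envelope and band-pass it around the syllabic rate
#'
#' The envelope is resampled (polyphase, anti-aliased) to `target_hz` and
#' then band-pass filtered with a 2nd-order Butterworth applied
#' forward-backward (zero phase), so that no group delay is introduced
#' between the heard and produced envelopes. Defaults are 100 Hz and
#' 3.5-5.5 Hz, bracketing the 4.3-4.7 Hz stimulus rates.
#'
#' @param env An [envelope_series].
#' @param target_hz Target sampling rate in Hz (default 100).
#' @param band Length-2 numeric `(low_hz, high_hz)` pass band (default
#'   `c(3.5, 5.5)`).
#' @return A band-passed [envelope_series] at `target_hz`.
#' @export
resample_and_band <- function(env, target_hz = 100, band = c(3.5, 5.5)) {
  stopifnot(inherits(env, "envelope_series"), target_hz > 0)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= target_hz / 2) {
    stop("band must satisfy 0 < low < high < target_hz/2")
  }
  x <- resample_uniform(env$values, env$sample_rate_hz, target_hz)
  bf <- signal::butter(2, band / (target_hz / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  out <- envelope_series(y, target_hz, env$source_id, bandpassed = TRUE)
  out
}

# Polyphase anti-aliased resampling with a linear-phase FIR (Hamming-window
# design, cutoff at 90% of the narrower Nyquist), delay-compensated so the
# output is phase-aligned with the input; trimmed/padded to
# round(duration * target_hz) samples.
resample_uniform <- function(x, from_hz, to_hz) {
  if (isTRUE(all.equal(from_hz, to_hz))) return(x)
  n_out <- round(length(x) / from_hz * to_hz)
  frac <- gcd_frac(to_hz, from_hz)
  p <- frac$p; q <- frac$q
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, length(up), p)] <- x
  ord <- 20 * max(p, q)
  h <- p * signal::fir1(ord, 0.9 / max(p, q))
  y <- signal::fftfilt(h, c(up, numeric(ord)))
  y <- y[(ord / 2 + 1):(ord / 2 + n * p)]
  y <- y[seq(1, length(y), q)]
  if (length(y) >= n_out) y[seq_len(n_out)] else
    c(y, rep(y[length(y)], n_out - length(y)))
}

gcd_frac <- function(a, b, tol = 1e-9) {
  # rational p/q ~ a/b with small integers (rates are typically integer Hz)
  r <- a / b
  for (q in 1:10000) {
    p <- round(r * q)
    if (abs(p / q - r) < tol && p > 0) return(list(p = p, q = q))
  }
  stop("cannot express rate ratio ", r, " as a small fraction")
}

#' Instantaneous phase of a band-limited envelope
#'
#' Phase of the analytic signal of the (band-passed, zero-mean) envelope, in
#' radians, wrapped to (-pi, pi]. For a constant (numerically zero) input the
#' phase is undefined; the phase of the near-zero analytic part is returned
#' and downstream PLVs on such input are unreliable.
#'
#' @param env A band-passed [envelope_series].
#' @return Numeric vector of phases in radians.
#' @export
extract_phase <- function(env) {
  stopifnot(inherits(env, "envelope_series"))
  Arg(hilbert_analytic(env$values))
}

#' Windowed phase-locking value
#'
#' For each analysis window the PLV is the modulus of the mean unit phasor of
#' the phase difference,
#' \deqn{\mathrm{PLV} = \frac{1}{T}\left|\sum_{t=1}^{T}
#'   e^{i(\theta_1(t) - \theta_2(t))}\right|,}
#' computed over that window's `T` samples. Windows are `window_s` long and
#' adjacent windows share `overlap_s` seconds (hop = `window_s - overlap_s`);
#' only complete windows enter the mean, which is the participant's PLV.
#'
#' @param pair A [phase_pair].
#' @param window_s Window length in seconds (default 5).
#' @param overlap_s Overlap between adjacent windows in seconds (default 2).
#' @return An object of class `plv_result` with fields `plv_mean`,
#'   `plv_windows`, `window_s`, `overlap_s`, `n_windows`.
#' @export
compute_plv <- function(pair, window_s = 5, overlap_s = 2) {
  stopifnot(inherits(pair, "phase_pair"))
  if (window_s <= 0 || overlap_s < 0 || overlap_s >= window_s) {
    stop("need 0 <= overlap_s < window_s")
  }
  fs <- pair$sample_rate_hz
  win <- round(window_s * fs)
  hop <- round((window_s - overlap_s) * fs)
  if (pair$T < win) stop("signal shorter than one analysis window")
  starts <- seq(1, pair$T - win + 1, by = hop)
  dphi <- pair$theta1 - pair$theta2
  plvs <- vapply(starts, function(s) {
    w <- dphi[s:(s + win - 1)]
    Mod(mean(exp(1i * w)))
  }, numeric(1))
  structure(
    list(plv_mean = mean(plvs), plv_windows = plvs,
         window_s = window_s, overlap_s = overlap_s,
         n_windows = length(plvs)),
    class = "plv_result"
  )
}

#' @export
print.plv_result <- function(x, ...) {
  cat(sprintf("<plv_result> mean PLV = %.3f over %d windows (%g s / %g s overlap)\n",
              x$plv_mean, x$n_windows, x$window_s, x$overlap_s))
  invisible(x)
}

#' Normalized spectral profile of a produced-speech envelope
#'
#' Discrete Fourier transform of the broadband (unfiltered) envelope, no
#' windowing; power is restricted to frequency bins in `[1, 10]` Hz and
#' normalized to sum to 1.
#'
#' @param env A broadband [envelope_series] (not band-passed).
#' @param freq_range Length-2 numeric; bins kept, default `c(1, 10)` Hz.
#' @return An object of class `spectrum_result` with `freqs_hz` and `power`.
#' @export
spectral_profile <- function(env, freq_range = c(1, 10)) {
  stopifnot(inherits(env, "envelope_series"))
  n <- length(env$values)
  X <- stats::fft(env$values)
  freqs <- (seq_len(n) - 1) * env$sample_rate_hz / n
  keep <- freqs >= freq_range[1] & freqs <= freq_range[2]
  if (!any(keep)) stop("no DFT bins inside the frequency range")
  p <- Mod(X[keep])^2
  structure(
    list(freqs_hz = freqs[keep], power = p / sum(p), group = NULL),
    class = "spectrum_result"
  )
}

#' Group-averaged spectra with dispersion
#'
#' Averages per-participant normalized spectra within groups (e.g. high vs
#' low synchronizers), returning the mean and standard deviation per
#' frequency bin.
#'
#' @param spectra List of [spectral_profile()] results on a common grid.
#' @param labels Group label per spectrum.
#' @return A list of `spectrum_result` objects (one per group) with an added
#'   `power_sd` field.
#' @export
group_average_spectra <- function(spectra, labels) {
  stopifnot(length(spectra) == length(labels), length(spectra) > 0)
  grid <- spectra[[1]]$freqs_hz
  for (s in spectra) {
    if (length(s$freqs_hz) != length(grid) ||
        max(abs(s$freqs_hz - grid)) > 1e-9) {
      stop("spectra are not on a common frequency grid")
    }
  }
  labels <- as.character(labels)
  out <- list()
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) == 0) stop("empty group: ", g)
    mat <- do.call(rbind, lapply(spectra[idx], function(s) s$power))
    out[[g]] <- structure(
      list(freqs_hz = grid,
           power = colMeans(mat),
           power_sd = if (length(idx) == 1) rep(0, ncol(mat)) else
             apply(mat, 2, stats::sd),
           group = g, n = length(idx)),
      class = "spectrum_result"
    )
  }
  out
}
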