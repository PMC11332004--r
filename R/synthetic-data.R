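#' Specification of an accelerating syllable-train stimulus
#'
#' The SSS stimulus is a syllable stream whose rate steps through a sequence
#' of constant-rate plateaus. The default models the accelerated test:
#' 4.3 to 4.7 Hz in 0.1 Hz steps. With the default 12 s plateaus the stream
#' lasts exactly 60 s; `plateau_s = 10` gives the 50 s variant.
#'
#' @param rates_hz Strictly increasing syllable rates, Hz.
#' @param plateau_s Duration of each constant-rate plateau, seconds.
#' @param sample_rate_hz Envelope sampling rate, Hz.
#' @return An object of class `stimulus_spec`; `total_s` is derived.
#' @export
stimulus_spec <- function(rates_hz = c(4.3, 4.4, 4.5, 4.6, 4.7),
                          plateau_s = 12, sample_rate_hz = 1000) {
  if (length(rates_hz) == 0) stop("rates_hz must be non-empty")
  if (any(diff(rates_hz) <= 0)) stop("rates_hz must be strictly increasing")
  if (any(rates_hz <= 0)) stop("rates_hz must be positive")
  if (plateau_s <= 0) stop("plateau_s must be positive")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  structure(
    list(rates_hz = rates_hz, plateau_s = plateau_s,
         sample_rate_hz = sample_rate_hz,
         total_s = length(rates_hz) * plateau_s),
    class = "stimulus_spec"
  )
}

#' Generate the amplitude envelope of an accelerating syllable train
#'
#' Concatenates constant-rate plateaus with no gaps; each syllable
#' contributes one raised-cosine (Hann) burst. The number of syllables in a
#' plateau is `floor(plateau_s * rate)`.
#'
#' @param spec A [stimulus_spec].
#' @param burst_width_s Burst duration, seconds (default 0.11, roughly one
#'   "ta").
#' @return A nonnegative [envelope_series]; syllable onset times and rates
#'   are attached as the `"syllables"` attribute (a data frame with columns
#'   `time_s`, `rate_hz`).
#' @export
generate_stimulus_envelope <- function(spec, burst_width_s = 0.11) {
  stopifnot(inherits(spec, "stimulus_spec"), burst_width_s > 0)
  fs <- spec$sample_rate_hz
  n <- round(spec$total_s * fs)
  values <- numeric(n)
  syl_t <- numeric(0)
  syl_r <- numeric(0)
  offset <- 0
  for (r in spec$rates_hz) {
    k <- floor(spec$plateau_s * r)
    centers <- offset + (seq_len(k) - 0.5) / r
    syl_t <- c(syl_t, centers)
    syl_r <- c(syl_r, rep(r, k))
    offset <- offset + spec$plateau_s
  }
  values <- add_bursts(values, fs, syl_t, burst_width_s)
  env <- envelope_series(values, fs, "stimulus")
  attr(env, "syllables") <- data.frame(time_s = syl_t, rate_hz = syl_r)
  env
}

# Superimpose Hann bursts of width w centered at `centers` (seconds).
add_bursts <- function(values, fs, centers, w) {
  n <- length(values)
  half <- w / 2
  for (t0 in centers) {
    i0 <- max(1L, floor((t0 - half) * fs) + 1L)
    i1 <- min(n, ceiling((t0 + half) * fs))
    if (i0 > i1) next
    t <- (seq(i0, i1) - 1) / fs
    u <- (t - t0) / w   # in [-1/2, 1/2] inside the burst
    b <- ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
    values[i0:i1] <- pmax(values[i0:i1], b)
  }
  values
}

#' Specification of a simulated participant
#'
#' Two production modes: `"coupled"` participants place each burst at the
#' stimulus syllable time plus von Mises phase jitter of concentration
#' `coupling_kappa` (large kappa = tight locking, kappa = 0 = uniform
#' jitter, emulating high vs very low synchronizers); `"self_paced"`
#' participants whisper at their own constant rate regardless of the
#' stimulus, with the same von Mises jitter modelling motor variability
#' about their intrinsic beat.
#'
#' @param coupling_kappa von Mises concentration, >= 0.
#' @param mode `"coupled"` or `"self_paced"`.
#' @param self_rate_hz Intrinsic rate for self-paced mode, in `[3, 6]` Hz.
#' @param burst_width_s Burst width, seconds.
#' @param seed RNG seed; a fixed seed makes the production reproducible.
#' @return An object of class `participant_spec`.
#' @export
participant_spec <- function(coupling_kappa = 16, mode = c("coupled", "self_paced"),
                             self_rate_hz = 4.5, burst_width_s = 0.11,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (coupling_kappa < 0) stop("coupling_kappa must be >= 0")
  if (self_rate_hz < 3 || self_rate_hz > 6) {
    stop("self_rate_hz must lie in [3, 6] Hz")
  }
  structure(
    list(coupling_kappa = coupling_kappa, mode = mode,
         self_rate_hz = self_rate_hz, burst_width_s = burst_width_s,
         seed = seed),
    class = "participant_spec"
  )
}

#' Simulate a participant's produced-speech envelope
#'
#' Returns a burst-train envelope on the same time grid as the stimulus.
#' Coupled mode jitters each stimulus syllable by a von Mises phase draw
#' (concentration `coupling_kappa`) converted to time through the local
#' syllable rate; self-paced mode ignores the stimulus timing entirely.
#'
#' @param stim A stimulus [envelope_series], normally from
#'   [generate_stimulus_envelope()] (syllable times are taken from its
#'   `"syllables"` attribute, or recovered from envelope peaks).
#' @param spec A [participant_spec].
#' @return An [envelope_series] with `source_id` `"production"`.
#' @export
simulate_production <- function(stim, spec) {
  stopifnot(inherits(stim, "envelope_series"), inherits(spec, "participant_spec"))
  fs <- stim$sample_rate_hz
  dur <- envelope_duration(stim)
  syl <- attr(stim, "syllables")
  if (is.null(syl)) syl <- find_envelope_peaks(stim)

  centers <- with_seed(spec$seed, {
    if (spec$mode == "coupled") {
      jitter_phase <- rvonmises(nrow(syl), spec$coupling_kappa)
      syl$time_s + jitter_phase / (2 * pi * syl$rate_hz)
    } else {
      k <- floor(dur * spec$self_rate_hz)
      beat <- (seq_len(k) - 0.5) / spec$self_rate_hz
      # motor variability about the intrinsic beat, same concentration knob
      beat + rvonmises(k, spec$coupling_kappa) / (2 * pi * spec$self_rate_hz)
    }
  })
  centers <- centers[centers >= 0 & centers <= dur]
  values <- add_bursts(numeric(length(stim$values)), fs, centers,
                       spec$burst_width_s)
  out <- envelope_series(values, fs, "production")
  attr(out, "burst_times") <- centers
  out
}

# Recover syllable times/rates from envelope local maxima (fallback when the
# stimulus did not come from generate_stimulus_envelope).
find_envelope_peaks <- function(env) {
  x <- env$values
  fs <- env$sample_rate_hz
  thr <- 0.5 * max(x)
  is_peak <- c(FALSE, diff(sign(diff(x))) < 0, FALSE) & x > thr
  t <- (which(is_peak) - 1) / fs
  # enforce a minimum separation of 0.1 s
  if (length(t) > 1) {
    keep <- c(TRUE, diff(t) > 0.1)
    t <- t[keep]
  }
  if (length(t) < 2) stop("cannot locate syllable peaks in stimulus envelope")
  rate <- 1 / stats::median(diff(t))
  data.frame(time_s = t, rate_hz = rate)
}

#' Draw from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n Number of draws.
#' @param kappa Concentration, >= 0.
#' @param mu Mean direction, radians.
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1
    }
  }
  wrap_pi(out + mu)
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y <= -pi, y + 2 * pi, y)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a simulated PLV cohort
#'
#' PLVs are drawn from a two-component Gaussian mixture truncated to
#' `[0, 1]` by resampling (no point mass at the bounds). Component 1 is the
#' low-synchronizer component, component 2 the high one. Defaults mirror the
#' fitted structure of an English-stimulus cohort: weights 0.62/0.38, means
#' 0.48/0.77, standard deviations 0.106/0.045, and a strong sex imbalance
#' across groups.
#'
#' @param n Number of participants.
#' @param weights Two mixing weights summing to 1 (low, high).
#' @param means Two component means in PLV units, each in (0, 1).
#' @param sds Two component standard deviations, each in (0, 1).
#' @param sex_probs_by_group Probability of a male participant given group,
#'   named `c(low = , high = )`.
#' @param cohort Cohort label stored in the table.
#' @param covariate_seed RNG seed for all draws.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n = 61,
                            weights = c(0.62, 0.38),
                            means = c(0.48, 0.77),
                            sds = c(0.106, 0.045),
                            sex_probs_by_group = c(low = 5 / 36, high = 14 / 25),
                            cohort = "english",
                            covariate_seed = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (length(weights) != 2 || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be two values summing to 1")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (length(means) != 2 || any(means <= 0) || any(means >= 1)) {
    stop("means must lie in (0, 1)")
  }
  if (length(sds) != 2 || any(sds <= 0) || any(sds >= 1)) {
    stop("sds must lie in (0, 1)")
  }
  structure(
    list(n = as.integer(n), weights = weights, means = means, sds = sds,
         sex_probs_by_group = sex_probs_by_group, cohort = cohort,
         covariate_seed = covariate_seed),
    class = "cohort_sim_spec"
  )
}

#' Simulate a cohort table of PLVs and covariates
#'
#' Draws `n` PLVs from the truncated two-component mixture, records the
#' generating component as ground truth (`plv_true_group`), and draws
#' covariates with group-dependent structure: sex (per
#' `sex_probs_by_group`), age, years of education, years of musical training
#' (zero-inflated exponential), ordinal musical expertise level (0-5), and a
#' perceived-change flag.
#'
#' @param spec A [cohort_sim_spec].
#' @return A `data.frame` cohort table; zero rows when `n = 0`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  n <- spec$n
  if (n == 0) {
    return(data.frame(participant_id = character(0), cohort = character(0),
                      plv = numeric(0), plv_true_group = character(0),
                      sex = character(0), age = numeric(0),
                      edu_years = numeric(0), music_years = numeric(0),
                      music_level = integer(0), perceived_change = logical(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(spec$covariate_seed, {
    comp <- sample.int(2, n, replace = TRUE, prob = spec$weights)
    plv <- vapply(comp, function(k) {
      rtruncnorm01(spec$means[k], spec$sds[k])
    }, numeric(1))
    grp <- c("low", "high")[comp]
    p_male <- spec$sex_probs_by_group[grp]
    sex <- ifelse(stats::runif(n) < p_male, "male", "female")
    age <- pmax(18, round(stats::rnorm(n, mean = ifelse(grp == "high", 23.5, 24),
                                       sd = ifelse(grp == "high", 3.0, 7.6))))
    edu <- pmax(10, round(stats::rnorm(n, mean = ifelse(grp == "high", 16, 15),
                                       sd = ifelse(grp == "high", 2.2, 2.4))))
    p0 <- 0.2  # fraction with no musical training
    mu_music <- ifelse(grp == "high", 7.0, 6.7) / (1 - p0)
    music <- ifelse(stats::runif(n) < p0, 0,
                    round(stats::rexp(n, rate = 1 / mu_music)))
    level <- stats::rbinom(n, 5, ifelse(grp == "high", 2.6, 1.7) / 5)
    perceived <- stats::runif(n) < 0.21
    data.frame(
      participant_id = sprintf("%s_%03d", spec$cohort, seq_len(n)),
      cohort = spec$cohort, plv = plv, plv_true_group = grp,
      sex = sex, age = age, edu_years = edu, music_years = music,
      music_level = level, perceived_change = perceived,
      stringsAsFactors = FALSE
    )
  })
}

# One draw from N(mean, sd) truncated to [0, 1] by resampling.
rtruncnorm01 <- function(mean, sd) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= 0 && x <= 1) return(x)
  }
}
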