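test_that("envelope of a pure tone is its amplitude", {
  fs <- 8000
  t <- seq(0, 1, by = 1 / fs)
  sig <- audio_signal(sin(2 * pi * 1000 * t), fs, "tone")
  env <- extract_envelope(sig)
  mid <- seq(round(0.1 * fs), round(0.9 * fs))
  expect_true(all(abs(env$values[mid] - 1) < 0.01))
})

test_that("envelope of an AM tone peaks at the modulation frequency", {
  fs <- 2000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  carrier <- sin(2 * pi * 400 * t)
  x <- (1 + 0.8 * sin(2 * pi * 4.5 * t)) * carrier
  env <- extract_envelope(audio_signal(x, fs, "am"))
  spec <- spectral_profile(env)
  expect_equal(spec$freqs_hz[which.max(spec$power)], 4.5, tolerance = 0.05)
})

test_that("envelope of silence is silence", {
  env <- extract_envelope(audio_signal(numeric(4000), 8000, "z"))
  expect_true(all(env$values < 1e-12))
})

test_that("band-pass retains the syllabic band and rejects distant rates", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  mk <- function(f) envelope_series(1 + 0.5 * sin(2 * pi * f * t), fs, "e")
  mid <- function(v) v[seq(500, length(v) - 500)]

  in_band <- resample_and_band(mk(4.5))
  expect_equal(in_band$sample_rate_hz, 100)
  expect_equal(length(in_band$values), 3000)
  amp45 <- max(abs(mid(in_band$values)))
  expect_equal(amp45, 0.5, tolerance = 0.05)

  out_band <- resample_and_band(mk(1.0))
  amp1 <- max(abs(mid(out_band$values)))
  expect_lt(amp1 * 10, amp45)

  expect_error(resample_and_band(mk(4.5), band = c(5.5, 3.5)), "band")
  expect_error(resample_and_band(mk(4.5), band = c(3.5, 60)), "band")
})

test_that("instantaneous phase advances at the oscillation frequency", {
  fs <- 100
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  env <- envelope_series(sin(2 * pi * 4.5 * t), fs, "e", bandpassed = TRUE)
  ph <- extract_phase(env)
  mid <- seq(200, length(ph) - 200)
  slope <- mean(diff(signal::unwrap(ph[mid]))) * fs
  expect_equal(slope, 2 * pi * 4.5, tolerance = 0.01 * 2 * pi * 4.5)

  # negation shifts phase by pi (mod 2pi)
  neg <- extract_phase(envelope_series(-sin(2 * pi * 4.5 * t), fs, "e",
                                       bandpassed = TRUE))
  dphi <- (neg - ph)[mid] %% (2 * pi)
  expect_true(all(abs(dphi - pi) < 1e-6))
})

test_that("PLV matches the definition on canonical phase configurations", {
  fs <- 100
  n <- 1100
  th <- cumsum(rnorm(n, 0.28, 0.1))
  # identical phases: every window PLV is 1
  r <- compute_plv(phase_pair(th, th, fs))
  expect_equal(r$plv_windows, rep(1, r$n_windows))
  expect_equal(r$plv_mean, 1)
  # constant offset: still 1
  r2 <- compute_plv(phase_pair(th, th + 1.23, fs))
  expect_equal(r2$plv_mean, 1)
  # 11 s at 100 Hz, 5 s windows, 3 s hop: windows start at 0, 3, 6 s
  expect_equal(r$n_windows, 3)
  # equal numbers of 0 and pi differences cancel within one window
  half <- 250
  th2 <- th[1:500] - rep(c(0, pi), each = half)
  r3 <- compute_plv(phase_pair(th[1:500], th2, fs))
  expect_equal(r3$plv_windows[1], 0, tolerance = 1e-12)
})

test_that("PLV of independent uniform phases matches the small-sample mean", {
  # E[PLV] for T independent uniform phase differences is (sqrt(pi)/2)/sqrt(T)
  fs <- 100
  T_win <- 500
  set.seed(314)
  plvs <- replicate(200, {
    pair <- phase_pair(runif(T_win, -pi, pi), runif(T_win, -pi, pi), fs)
    compute_plv(pair)$plv_mean
  })
  expect_equal(mean(plvs), (sqrt(pi) / 2) / sqrt(T_win), tolerance = 0.04)
})

test_that("windowed PLV equals brute-force evaluation of the formula", {
  set.seed(99)
  for (i in 1:200) {
    fs <- sample(c(50, 100), 1)
    dur <- runif(1, 6, 20)
    n <- round(dur * fs)
    th1 <- runif(n, -pi, pi)
    th2 <- cumsum(rnorm(n, 0.2, 0.3))
    win <- sample(c(3, 5), 1)
    ov <- sample(c(0, 1, 2), 1)
    got <- compute_plv(phase_pair(th1, th2, fs), win, ov)
    want <- plv_brute_force(th1, th2, fs, win, ov)
    expect_equal(got$plv_windows, want, tolerance = 1e-12)
    expect_equal(got$plv_mean, mean(want), tolerance = 1e-12)
    expect_true(all(got$plv_windows >= 0 & got$plv_windows <= 1))
  }
})

test_that("PLV is symmetric and shift invariant", {
  set.seed(7)
  fs <- 100
  th1 <- cumsum(rnorm(900, 0.3, 0.2))
  th2 <- cumsum(rnorm(900, 0.28, 0.2))
  a <- compute_plv(phase_pair(th1, th2, fs))
  b <- compute_plv(phase_pair(th2, th1, fs))
  expect_equal(a$plv_windows, b$plv_windows, tolerance = 1e-12)
  d <- compute_plv(phase_pair(th1 + 0.7, th2 + 0.7, fs))
  expect_equal(a$plv_windows, d$plv_windows, tolerance = 1e-12)
  # mean lies within the per-window range
  expect_gte(a$plv_mean, min(a$plv_windows))
  expect_lte(a$plv_mean, max(a$plv_windows))
})

test_that("signals shorter than one window are rejected", {
  expect_error(compute_plv(phase_pair(runif(300), runif(300), 100)),
               "shorter")
  expect_error(phase_pair(runif(10), runif(9), 100), "equal length")
})

test_that("spectral profile is normalized and localizes a pure oscillation", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  env <- envelope_series(1 + 0.5 * sin(2 * pi * 4.5 * t), fs, "e")
  spec <- spectral_profile(env)
  expect_equal(sum(spec$power), 1, tolerance = 1e-9)
  expect_true(all(spec$freqs_hz >= 1 & spec$freqs_hz <= 10))
  expect_equal(spec$freqs_hz[which.max(spec$power)], 4.5, tolerance = 0.05)
})

test_that("white-noise envelopes have no dominant spectral bin", {
  # single raw periodograms fluctuate (exponential bins), so the flatness
  # check applies to the spectrum averaged over independent noise draws
  set.seed(21)
  specs <- lapply(1:20, function(i) {
    spectral_profile(envelope_series(abs(rnorm(3000)) + 0.1, 100, "n"))
  })
  avg <- group_average_spectra(specs, rep("noise", 20))$noise
  expect_lt(max(avg$power), 5 * median(avg$power))
})

test_that("group-averaged spectra separate tight from variable producers", {
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  mk_spec <- function(jitter_sd, seed) {
    set.seed(seed)
    f_inst <- 4.5 + jitter_sd * cumsum(rnorm(length(t))) / sqrt(seq_along(t))
    env <- envelope_series(1 + 0.5 * sin(2 * pi * cumsum(f_inst) / fs), fs, "e")
    spectral_profile(env)
  }
  highs <- lapply(1:5, function(s) mk_spec(0.002, s))
  lows <- lapply(1:5, function(s) mk_spec(0.2, s + 100))
  avg <- group_average_spectra(c(highs, lows), rep(c("high", "low"), each = 5))
  sharp <- function(g) max(avg[[g]]$power) / median(avg[[g]]$power)
  expect_gt(sharp("high"), sharp("low"))

  # identical spectra have zero dispersion
  same <- group_average_spectra(list(highs[[1]], highs[[1]]), c("g", "g"))
  expect_true(all(same$g$power_sd == 0))

  expect_error(group_average_spectra(list(), character(0)))
  short <- spectral_profile(envelope_series(abs(rnorm(500)) + 0.1, 100, "x"))
  expect_error(group_average_spectra(list(highs[[1]], short), c("a", "b")),
               "grid")
})
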