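test_that("stimulus envelope has the designed syllable count and duration", {
  # 10 s plateaus at 4.3..4.7 Hz: floor(10 r) syllables each = 43+44+45+46+47
  env <- quick_stimulus(plateau_s = 10, fs = 200)
  syl <- attr(env, "syllables")
  expect_equal(nrow(syl), 225)
  expect_equal(envelope_duration(env), 50)
  # count envelope peaks independently of the attribute
  x <- env$values
  peaks <- which(diff(sign(diff(x))) < 0) + 1
  peaks <- peaks[x[peaks] > 0.5 * max(x)]
  peaks <- peaks[c(TRUE, diff(peaks) > 0.05 * 200)]
  expect_equal(length(peaks), 225)

  single <- generate_stimulus_envelope(stimulus_spec(4.5, plateau_s = 12,
                                                     sample_rate_hz = 200))
  expect_equal(nrow(attr(single, "syllables")), 54)
  expect_equal(envelope_duration(single), 12)
})

test_that("stimulus configuration is validated", {
  expect_error(stimulus_spec(numeric(0)), "non-empty")
  expect_error(stimulus_spec(c(4.5, 4.4)), "increasing")
  expect_error(stimulus_spec(4.5, plateau_s = 0), "positive")
  # default design: five plateaus of 12 s = one minute
  expect_equal(stimulus_spec()$total_s, 60)
})

test_that("generated envelopes are nonnegative and finite", {
  for (fs in c(100, 250)) {
    env <- quick_stimulus(fs = fs)
    expect_true(all(is.finite(env$values)))
    expect_true(all(env$values >= 0))
    prod <- simulate_production(env, participant_spec(seed = 11))
    expect_true(all(is.finite(prod$values)))
    expect_true(all(prod$values >= 0))
  }
})

test_that("production is bit-reproducible under a fixed seed", {
  env <- quick_stimulus(fs = 100)
  a <- simulate_production(env, participant_spec(coupling_kappa = 4, seed = 99))
  b <- simulate_production(env, participant_spec(coupling_kappa = 4, seed = 99))
  expect_identical(a$values, b$values)
  c <- simulate_production(env, participant_spec(coupling_kappa = 4, seed = 100))
  expect_false(identical(a$values, c$values))
})

test_that("unknown production mode is rejected", {
  expect_error(participant_spec(mode = "telepathic"))
  expect_error(participant_spec(coupling_kappa = -1), "kappa")
  expect_error(participant_spec(self_rate_hz = 2.5), "3, 6")
})

test_that("downstream PLV is monotone in the coupling concentration", {
  stim <- quick_stimulus(fs = 100)
  kappas <- c(0, 1, 4, 16, 1e6)
  seeds <- 1:20
  mean_plv <- vapply(kappas, function(k) {
    mean(vapply(seeds, function(s) simulated_plv(stim, kappa = k, seed = s),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_plv) >= 0))
  expect_gte(mean_plv[5], 0.95)   # jitter-free alignment locks
  expect_lte(mean_plv[1], 0.4)    # uniform jitter destroys locking
})

test_that("self-paced production at the plateau rate locks on that plateau", {
  # a single 4.5 Hz plateau, intrinsic rate 4.5 Hz: locked by construction
  stim <- generate_stimulus_envelope(stimulus_spec(4.5, plateau_s = 12,
                                                   sample_rate_hz = 100))
  plv <- simulated_plv(stim, kappa = 1e6, mode = "self_paced",
                       self_rate = 4.5, seed = 2)
  expect_gte(plv, 0.9)
})

test_that("von Mises sampler matches its distribution", {
  set.seed(42)
  th <- rvonmises(20000, kappa = 4)
  expect_true(all(th > -pi & th <= pi))
  # circular mean resultant length R = I1(k)/I0(k); for k = 4: 0.8635
  R <- Mod(mean(exp(1i * th)))
  expect_equal(R, besselI(4, 1) / besselI(4, 0), tolerance = 0.01)
  expect_equal(Arg(mean(exp(1i * th))), 0, tolerance = 0.02)
  # kappa = 0 reduces to the uniform circle
  set.seed(43)
  u <- rvonmises(20000, kappa = 0)
  expect_lt(Mod(mean(exp(1i * u))), 0.02)
})

test_that("cohort simulation honors weights, truncation and ground truth", {
  # degenerate weights: every draw from the (low) first component
  co <- simulate_cohort(cohort_sim_spec(n = 50, weights = c(1, 0),
                                        covariate_seed = 7))
  expect_true(all(co$plv_true_group == "low"))

  # empty cohort is a well-formed empty table
  co0 <- simulate_cohort(cohort_sim_spec(n = 0))
  expect_equal(nrow(co0), 0)
  expect_true(all(c("participant_id", "plv", "plv_true_group") %in% names(co0)))

  # law of large numbers: per-component sample means near generating means
  co <- simulate_cohort(cohort_sim_spec(
    n = 1000, weights = c(0.6, 0.4), means = c(0.48, 0.77),
    sds = c(0.10, 0.05), covariate_seed = 123))
  expect_true(all(co$plv >= 0 & co$plv <= 1))
  expect_equal(mean(co$plv[co$plv_true_group == "low"]), 0.48, tolerance = 0.02 / 0.48)
  expect_equal(mean(co$plv[co$plv_true_group == "high"]), 0.77, tolerance = 0.02 / 0.77)
  # empirical mixture proportion converges to the weight
  expect_equal(mean(co$plv_true_group == "low"), 0.6, tolerance = 0.05)

  expect_error(cohort_sim_spec(weights = c(0.7, 0.6)), "summing to 1")
})

test_that("cohort covariates carry group-dependent structure", {
  co <- simulate_cohort(cohort_sim_spec(n = 2000, covariate_seed = 5))
  p_male <- tapply(co$sex == "male", co$plv_true_group, mean)
  expect_gt(p_male[["high"]], p_male[["low"]])
  expect_true(all(co$age >= 18))
  expect_true(all(co$music_level %in% 0:5))
})
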