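# Build a manifest of simulated participants: envelope CSVs on disk plus
# covariates, against a shared stimulus envelope (written once).
build_synthetic_manifest <- function(dir, n_coupled, n_selfpaced, fs = 200,
                                     kappa = 16, off_rate = 3.6,
                                     seed0 = 100) {
  stim <- generate_stimulus_envelope(
    stimulus_spec(plateau_s = 10, sample_rate_hz = fs))
  stim_path <- file.path(dir, "stimulus.csv")
  write_envelope_csv(stim, stim_path)
  rows <- list()
  add <- function(id, spec, group) {
    prod <- simulate_production(stim, spec)
    p <- file.path(dir, paste0(id, ".csv"))
    write_envelope_csv(prod, p)
    rows[[length(rows) + 1]] <<- data.frame(
      participant_id = id, path = p, true_group = group,
      sex = c("male", "female")[1 + length(rows) %% 2],
      age = 25, stringsAsFactors = FALSE)
  }
  # between-participant heterogeneity: coupling strengths and intrinsic
  # rates are drawn per participant (cohorts have a distribution of
  # coupling, not a point mass)
  set.seed(seed0)
  kappas <- exp(rnorm(n_coupled, log(kappa), 0.6))
  rates <- runif(n_selfpaced, off_rate, off_rate + 0.4)
  for (i in seq_len(n_coupled)) {
    add(sprintf("hi%02d", i),
        participant_spec(coupling_kappa = kappas[i], seed = seed0 + i),
        "coupled")
  }
  for (i in seq_len(n_selfpaced)) {
    add(sprintf("lo%02d", i),
        participant_spec(coupling_kappa = kappa, mode = "self_paced",
                         self_rate_hz = rates[i],
                         seed = seed0 + 500 + i), "self_paced")
  }
  list(manifest = do.call(rbind, rows), stimulus_path = stim_path)
}

# Synthetic stand-in for a deposited PLV table: two cohorts drawn at the
# reported mixture parameterizations.
synthetic_deposit <- function(seed = 1) {
  en <- simulate_cohort(cohort_sim_spec(
    n = 61, weights = c(0.62, 0.38), means = c(0.48, 0.77),
    sds = c(0.106, 0.045), cohort = "english", covariate_seed = seed))
  sw <- simulate_cohort(cohort_sim_spec(
    n = 60, weights = c(0.43, 0.57), means = c(0.38, 0.69),
    sds = c(0.096, 0.071), cohort = "swedish", covariate_seed = seed + 1))
  rbind(en, sw)[, c("participant_id", "cohort", "plv")]
}
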