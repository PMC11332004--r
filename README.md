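# speechsync

Analysis of the **speech-to-speech synchronization (SSS) test**: a short
behavioral protocol in which a participant whispers the syllable "ta" in
time with a syllable stream that accelerates from 4.3 to 4.7 syllables/s.
Individual synchronization ability is quantified by the **phase-locking
value (PLV)** between the envelopes of the heard and produced signals,

$$\mathrm{PLV} = \frac{1}{T}\left|\sum_{t=1}^{T}
  e^{i\,(\theta_1(t)-\theta_2(t))}\right|,$$

where θ₁ and θ₂ are the Hilbert phases of the two envelopes (resampled to
100 Hz, band-passed 3.5–5.5 Hz), evaluated in 5 s windows with 2 s overlap
and averaged. Across a cohort, PLVs are bimodal: a 1-D Gaussian mixture
fitted by EM (component count selected by AIC) splits participants into
**high** and **low synchronizers**, and a non-parametric statistical
battery (Kolmogorov–Smirnov with Monte-Carlo CIs, Mann–Whitney with
rank-biserial effect sizes, Fisher's exact test with Woolf odds-ratio CIs,
Spearman correlation, JZS Bayes factor) characterizes the group structure.

The package is for researchers running or re-analyzing SSS-style
experiments: it takes per-participant WAV recordings (or envelope CSVs)
plus a covariate table, applies the protocol's quality-control rules
(exclusion on > 4 s of silence), and produces per-participant PLVs, group
labels, and the full cohort statistics. A synthetic-data module simulates
the accelerating stimulus, phase-coupled productions (von Mises jitter
with concentration κ), and mixture-structured cohorts, so every stage is
testable without human data.

## Worked example

```r
library(speechsync)

## a 60 s accelerating stimulus and two simulated participants
stim <- generate_stimulus_envelope(stimulus_spec())       # 4.3..4.7 Hz
high <- simulate_production(stim, participant_spec(coupling_kappa = 16, seed = 1))
low  <- simulate_production(stim, participant_spec(mode = "self_paced",
                                                   self_rate_hz = 3.8, seed = 2))
participant_plv(stim, high)
#> <plv_result> mean PLV = 0.992 over 19 windows (5 s / 2 s overlap)
participant_plv(stim, low)
#> <plv_result> mean PLV = 0.071 over 19 windows (5 s / 2 s overlap)

## a simulated 61-participant cohort: mixture, labels, distribution test
cohort <- simulate_cohort(cohort_sim_spec(n = 61, covariate_seed = 8))
fit <- select_k_by_aic(cohort$plv, 1:3)
fit
#> <mixture_fit> k = 2, n = 61, AIC = -67.3937, converged
#>   component 1: weight 0.575, mean 0.476, sd 0.074
#>   component 2: weight 0.425, mean 0.765, sd 0.062
cls <- classify(fit, cohort$plv)
cls
#> <classification> 25 high / 36 low synchronizers (boundary PLV 0.635)
ks_one_sample(cohort$plv, n_sim = 10000, seed = 8)
#> <ks_result> D(61) = 0.634, p = 1.665e-15, CI [0, 0.0003688] (standard_normal)
```

The coupled participant locks to the stimulus (PLV ≈ 0.99) while the
self-paced one does not (PLV ≈ 0.07). The AIC comparison of 1–3 component
mixtures picks two components — the bimodal population structure — and the
posterior classification yields 25 high and 36 low synchronizers for this
draw. The KS statistic D doubles as a bounded effect size for
non-normality of the PLV distribution.

For a full run (QC → PLV → classification → statistics) build a manifest
CSV (`participant_id`, `path`, covariates) and call

```r
report <- run_pipeline(run_config(input_manifest = "manifest.csv",
                                  stimulus_path = "stimulus.wav",
                                  output_dir = "results"))
```

or use the command-line front-end `inst/scripts/sss-pipeline.R`
(subcommands `simulate`, `qc`, `plv`, `classify`, `stats`, `run`,
`replicate`). `replicate_from_deposit()` re-analyzes a deposited
per-participant PLV table and compares the recomputed group counts,
component means, weights, KS statistics and Bayes factor against the
reported reference values at their tolerances.

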