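---
title: "Measuring auditory-motor speech synchronization: methods and design choices"
author: "speechsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring auditory-motor speech synchronization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechsync)
```

## The measurement problem

In the speech-to-speech synchronization (SSS) test a participant whispers a
syllable ("ta") in time with a heard syllable stream whose rate steps from
4.3 to 4.7 syllables/s. The scientific quantity is how stably the
participant's produced rhythm locks to the heard rhythm. Across cohorts
this ability is not normally distributed: participants split into *high
synchronizers*, who spontaneously align their produced syllabic rate to the
stimulus, and *low synchronizers*, who do not — a bimodal population
structure that `speechsync` is built to measure, model and test.

The pipeline has four stages, each exposed as ordinary functions:

1. **Quality control** (`read_wav()`, `prefilter()`, `quality_check()`) —
   recordings are low-passed at 3 kHz and excluded if the speaker fell
   silent for more than 4 s (plus manual flags for loud speech and
   background noise, which require experimenter judgment).
2. **Synchrony measurement** (`extract_envelope()`, `resample_and_band()`,
   `extract_phase()`, `compute_plv()`) — the phase-locking value between
   the envelopes of the heard and produced signals.
3. **Classification** (`fit_gmm()`, `select_k_by_aic()`, `classify()`) —
   a one-dimensional Gaussian mixture over the cohort's PLVs, with the
   component count chosen by AIC, labels participants high or low.
4. **Cohort statistics** (`ks_one_sample()`, `ks_two_sample()`,
   `mann_whitney()`, `fisher_exact()`, `spearman_cor()`,
   `bayes_factor_ttest()`, `run_group_comparisons()`) — the distributional
   and group-difference battery.

A synthetic-data module (`generate_stimulus_envelope()`,
`simulate_production()`, `simulate_cohort()`) generates inputs with the
statistical structure the analysis assumes, so the entire pipeline is
testable without human recordings.

## The phase-locking value

For phase series $\theta_1(t)$ (heard) and $\theta_2(t)$ (produced) on a
shared grid of $T$ samples,

$$\mathrm{PLV} = \frac{1}{T}\left|\sum_{t=1}^{T}
  e^{i\,(\theta_1(t)-\theta_2(t))}\right| .$$

A PLV of 1 means a perfectly constant phase relation; independent phases
give values near $\tfrac{\sqrt{\pi}/2}{\sqrt{T}}$. The phases are obtained
by: Hilbert envelope of the (3 kHz low-passed) signal at its native rate →
resampling to 100 Hz → band-pass 3.5–5.5 Hz (bracketing the stimulus
rates) → Hilbert phase of the band-passed envelope. The PLV is evaluated
in 5 s windows that overlap by 2 s (hop 3 s); only complete windows are
kept, and their mean is the participant's score. Incomplete trailing
windows are discarded because the formula's $T$ is a per-window count and a
short window would be weighted inconsistently.

Parameters that matter, with defaults:

| parameter | default | units | why |
|---|---|---|---|
| `resample_hz` | 100 | Hz | envelope rhythm lives below 10 Hz; 100 Hz keeps filters well-conditioned |
| `band` | (3.5, 5.5) | Hz | brackets the 4.3–4.7 Hz stimulus rates |
| `window_s` / `overlap_s` | 5 / 2 | s | rate plateaus are ≥ 10 s; 5 s windows resolve drift without starving $T$ |
| `max_silence_s` | 4 | s | exclusion rule for non-compliant recordings (strictly "longer than") |
| `gmm_max_iter` | 140 | iterations | EM cap for the mixture fit |
| `mc_sims` | 10,000 | draws | Monte-Carlo confidence intervals at 95% |

## Numerical choices

* **Zero-phase filtering.** All filters (4th-order low-pass at 3 kHz,
  2nd-order band-pass at 3.5–5.5 Hz) are Butterworth designs applied
  forward–backward. Any one-directional IIR filter would delay the
  envelope by a frequency-dependent group delay and bias the phase
  difference between heard and produced signals; zero-phase application
  removes that bias at the cost of squaring the magnitude response.
* **Resampling.** Envelopes are resampled by an in-package polyphase
  routine: zero-stuffing to the rational upsampling factor, a linear-phase
  Hamming-window FIR anti-alias filter (cutoff at 90% of the narrower
  Nyquist, order 20·max(p, q)), and delay compensation by exactly half the
  filter order, so the resampled envelope is phase-aligned with the input.
  In-band amplitude error is below 0.2%.
* **Hilbert transform.** The analytic signal is built in the frequency
  domain (negative-frequency components zeroed). On a constant (all-zero)
  segment the instantaneous phase is undefined; the implementation returns
  the phase of the numerically-zero analytic part and PLVs computed from
  such input should not be interpreted.
* **Edge effects.** No samples are trimmed around the Hilbert/filtering
  edges; windows cover the full signal. This is a sensitivity knob:
  excluding the first and last half second changes simulated PLVs by well
  under the between-group separation.
* **EM details.** Initialization is deterministic: component means at the
  $k$ evenly-spaced sample quantiles, equal weights, pooled variance
  (optional seeded multi-start is available). Convergence is a relative
  log-likelihood change below 1e-6 within 140 iterations; the variance
  floor is 1e-6 (PLV² units) and a component hitting it is reported as
  non-convergence — the same behavior by which a 3-component model can
  drop out of the AIC comparison on strongly bimodal data. AIC is
  $2p - 2\ln L$ with $p = 3k - 1$ free parameters. Posterior ties in
  classification break toward "low" (conservative; a measure-zero event).
* **Mixture boundary.** `classify()` reports the PLV at which the two
  posterior probabilities cross between the component means, found by root
  bisection; if the posteriors do not cross there (extreme weight
  imbalance) the boundary is reported as `NA` while labels remain defined.

## Statistical battery

* **One-sample KS.** The empirical CDF of the raw PLVs is compared against
  the standard normal *without standardization*. PLVs live in [0, 1], so D
  is large (≈ 0.6) whenever the sample is concentrated there; the statistic
  doubles as a bounded effect size for non-normality. A fit-then-test
  variant (`standardize = TRUE`) is available, in which case the
  asymptotic p-value is anti-conservative and the Monte-Carlo machinery
  should be used instead.
* **Monte-Carlo confidence intervals** simulate the statistic under the
  null (10,000 seeded draws). What such an interval should bracket is
  genuinely ambiguous; the default brackets the Monte-Carlo estimate of
  the p-value (Clopper–Pearson), with a percentile interval of the null
  statistic distribution as an option.
* **Mann–Whitney U** with exact enumeration p-values for combined
  $n \le 16$ without ties, normal approximation with tie correction
  otherwise; effect size is the rank-biserial correlation
  $r = 1 - 2U/(n_1 n_2)$.
* **Fisher's exact test** reports the sample cross-product odds ratio with
  a Woolf log-normal interval
  $\exp(\ln \mathrm{OR} \pm z\sqrt{\sum 1/n_{ij}})$; the conditional-MLE
  estimate is also attached because the two estimators differ visibly in
  small samples. Zero cells produce a 0/infinite OR with a warning rather
  than a silent continuity correction.
* **Spearman correlation** uses average ranks for ties; its CI is the
  Fisher-z interval $\tanh(\operatorname{atanh}\rho \pm z/\sqrt{n-3})$.
* **JZS Bayes factor.** The two-sample null/alternative comparison uses a
  Cauchy prior (scale $\sqrt{2}/2$) on the standardized effect and a Welch
  (unequal-variance) t statistic with Welch degrees of freedom. The
  marginal likelihood under the alternative is the noncentral-t density
  mixed over the prior, integrated by adaptive quadrature at relative
  tolerance 1e-5; the posterior mean and credible interval of the effect
  come from the same quadrature on a grid.

## The synthetic-data generator

The generator emulates the study conditions:

* **Stimulus**: rate plateaus 4.3, 4.4, …, 4.7 Hz. The plateau duration is
  configurable because the protocol's "steps every 10 s" and its "1-min
  stream" are arithmetically incompatible for five plateaus; the default is
  12 s (exactly 60 s total), with 10 s as the literal alternative. Each
  syllable is a raised-cosine burst of 0.11 s — roughly one whispered
  "ta". Only the envelope periodicity matters downstream, so no speech
  synthesis is attempted.
* **Productions**: *coupled* participants place bursts at stimulus
  syllable times plus von Mises phase jitter with concentration
  $\kappa$ (the canonical circular noise family: one knob that maps
  monotonically to PLV, sampled by the Best–Fisher algorithm);
  *self-paced* participants burst at their own constant rate with the same
  jitter model for motor variability. $\kappa \to \infty$ gives PLV ≈ 1,
  $\kappa = 0$ destroys locking.
* **Cohorts**: PLVs from a two-component Gaussian mixture truncated to
  [0, 1] *by resampling* (clipping would create point masses at the
  bounds). Defaults mirror a fitted English-stimulus cohort: weights
  0.62/0.38, means 0.48/0.77, SDs 0.106/0.045, and strongly
  group-dependent sex proportions; age, education, musical training
  (zero-inflated exponential) and expertise (binomial ordinal 0–5) have
  group-dependent means. Cohort-level simulations draw per-participant
  coupling from a lognormal distribution around the nominal $\kappa$,
  because a cohort is a distribution of coupling strengths, not a point
  mass — with identical $\kappa$ for all, the within-group PLV spread is
  of order 1e-3 and a mixture component would sit on the variance floor.

What the generator does **not** emulate: whispered-speech acoustics,
amplitude variability between syllables, respiratory pauses, room noise,
or partial/intermittent coupling. Consequently simulated "lows"
(self-paced at an off-rate) score PLV ≈ 0.1, far lower than human low
synchronizers (≈ 0.5), and simulated groups separate much more cleanly
than human cohorts. Passing end-to-end tests therefore demonstrates that
the pipeline recovers the structure it is pointed at — not that it would
resolve subtler human group differences; that is what the deposit-based
replication mode (`replicate_from_deposit()`) is for.

## Problem sizes used in the tests

The test-suite simulations are sized to exercise each claim at desk scale:
oracle-equivalence suites use 100–200 random instances; mixture recovery
uses n = 1000 draws over 5 seeds; the end-to-end pipeline runs 10–60
simulated participants against a 50 s stimulus sampled at 200 Hz; KS/PLV
property checks use 20 seeds. The acceptance script mirrors these sizes
and completes in well under a minute.

## Known limitations

* The spectral module reports raw (unsmoothed, untapered) DFT power
  normalized over 1–10 Hz; single-participant spectra fluctuate
  accordingly, and flatness/peak statements are made about group averages.
* The one-sample KS convention (unstandardized standard-normal reference)
  is unusual outside this protocol family; interpret D as an effect size,
  not the Lilliefors statistic.
* The mixture model is strictly one-dimensional with at most three
  components, which is all the protocol calls for.
* `quality_check()` automates only the silence rule; loud-speech and
  background-noise exclusions remain manual flags informed by the reported
  RMS level.
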