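Package: speechsync
Title: Speech-to-Speech Synchronization Test Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the speech-to-speech synchronization
    (SSS) test: audio quality control, Hilbert-envelope phase extraction,
    windowed phase-locking values (PLV) between a heard syllable stream and
    a participant's whispered productions, classification of participants
    into high and low auditory-motor synchronizers by one-dimensional
    Gaussian-mixture modelling with AIC model selection, and the cohort-level
    non-parametric statistical battery (Kolmogorov-Smirnov, Mann-Whitney,
    Fisher exact, Spearman, JZS Bayes factor) with Monte-Carlo confidence
    intervals. Includes a synthetic-data generator producing accelerating
    syllable-train envelopes, phase-coupled simulated productions, and
    simulated cohorts so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
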