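Package: visuotrack
Title: Analysis of Visuo-Oculo-Manual Tracking Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying continuous visuomotor tracking, where a
    participant moves a cursor to follow a target driven by a sum of
    sinusoids while gaze is recorded. Provides the five standard
    pseudo-random harmonic target patterns, a configurable generative
    simulator of eye and hand tracking behavior (visuomotor delays,
    pursuit gain, catch-up saccades, motor noise), per-trial hand and
    gaze kinematic metrics (cursor-target distance, interleaved
    cross-correlation lag, lag-compensated residual error, binned power
    spectra, approximate entropy, submovement counts, onset latency,
    smooth-pursuit gain, saccadic rate), and the group-level statistics
    used to compare cohorts (pooled t-tests, Cohen's d, mixed-design
    ANOVA, per-group eye-hand correlations, age matching).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
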