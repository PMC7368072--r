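# visuotrack

Analysis toolkit for **visuo-oculo-manual tracking**: experiments in which a
participant moves a cursor (via a joystick held in the hand) to follow a
target that travels along a smooth, pseudo-random 2D path, while gaze is
recorded with an eye tracker. Such experiments are a workhorse of motor
control research because they expose the whole visuomotor loop — where the
eyes sample information, how fast visual information is turned into hand
commands, and how spatially accurate the resulting movement is — and they
are a natural setting for comparing groups, for example male and female
cohorts.

The package provides four layers:

1. **Target trajectories.** The five standard sum-of-sinusoids patterns,

   x(t) = A₁ₓ cos ωt + A₂ₓ cos(hₓωt − φₓ),
   y(t) = A₁ᵧ sin ωt + A₂ᵧ sin(hᵧωt − φᵧ),

   with ω = 2π/5 rad/s (one revolution per 5 s), amplitudes in cm and one
   second or third harmonic per axis (hₓ, hᵧ ∈ {2, 3}). Each pattern covers
   ≈160 cm in a 10-s trial, a mean tangential speed of ≈16 cm/s.
   (`load_pattern_table()`, `sample_trajectory()`, `path_length()`)

2. **A generative simulator** of tracking behavior: the cursor is a delayed,
   low-pass-filtered copy of the target plus band-limited motor noise, held
   still until an onset latency; gaze pursues the delayed target with a
   velocity gain below 1 and corrects the accumulating position error with
   predictive catch-up saccades. Whole cohorts are drawn with sex-specific
   parameter distributions (`simulate_trial()`, `simulate_cohort()`).

3. **Per-trial kinematic metrics.** Cursor–target distance; the temporal
   lag maximizing the interleaved (x,y) cross-correlation; the residual
   distance after lag compensation; tangential-velocity mean and SD; binned
   power spectra (18 bins, 0.11–1.98 Hz); approximate entropy; submovement
   counts from acceleration zero crossings; onset latency; saccade
   detection, saccadic rate, smooth-pursuit gain
   (`analyze_hand_trial()`, `analyze_gaze_trial()`).

4. **Group statistics.** Pooled two-sample t-tests with Cohen's d (raw
   values or printed summary statistics), mixed-design (split-plot) ANOVA
   for SEX × FREQUENCY / SEX × TRIAL designs, per-group eye–hand Pearson
   correlations, and greedy age matching
   (`t_test_summary()`, `mixed_anova_2way()`, `eye_hand_correlation()`,
   `age_match()`).

File-based pipeline wrappers tie the layers together: `run_simulate()`,
`run_analyze()`, `run_stats()`, `run_report()` write tidy CSV trials,
per-trial metric tables and a human-readable statistical report with full
provenance (version, seed, configuration hash).

## A worked example

```r
library(visuotrack)

# printed-style group summary: distance 1.87 ± 0.42 cm (n = 25 females)
# vs 1.62 ± 0.30 cm (n = 25 males)
t_test_summary(1.87, 0.42, 25, 1.62, 0.30, 25,
               metric = "cursor-target distance", label1 = "F", label2 = "M")
```

```
cursor-target distance: F = 1.87 ± 0.42 vs. M = 1.62 ± 0.3; t(48) = 2.42; p = 0.0193; d = 0.68
```

A 16% group difference in spatial tracking error, significant at α = 0.05
with a medium effect size. Simulating one participant's ten-trial block
with a 49-ms visuomotor delay and averaging the per-trial hand metrics,
as the analysis does:

```r
pats <- load_pattern_table()
hp <- hand_params(start_trim_s = 2)
rows <- do.call(rbind, lapply(1:10, function(i)
  analyze_hand_trial(simulate_trial(pats[[(i - 1) %% 5 + 1]],
                                    behavior_config(hand_lag_ms = 49),
                                    seed = i, participant_id = "M01",
                                    sex = "M", trial_index = i), hp)))
round(colMeans(rows[c("distance", "lag_ms", "xcorr_peak_r",
                      "residual_distance", "mean_tv")]), 3)
```

```
         distance            lag_ms      xcorr_peak_r residual_distance
            1.636            49.200             0.972             1.464
          mean_tv
           19.171
```

The estimated visuomotor lag (49.2 ms) recovers the configured 49-ms delay;
compensating it shrinks the tracking error from 1.64 to 1.46 cm — the same
decomposition into temporal and spatial error used to localize group
differences. An end-to-end cohort run (`run_report(out_dir = "...")`)
reproduces the study-level pattern: a clear group difference in
cursor–target lag, and a residual error that no longer separates the
groups once the lag is compensated.

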