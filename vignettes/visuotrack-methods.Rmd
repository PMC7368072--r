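---
title: "Models and methods behind visuotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind visuotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visuotrack)
```

This vignette is the package's account of its science: the target model,
the generative model of eye and hand behavior, how every metric is defined
and estimated, the numerical choices behind them, and what the simulation
does and does not establish about real data.

## The task and the target model

In a visuo-oculo-manual tracking trial a participant holds a joystick and
moves a cursor to follow a target on a screen; gaze may be recorded
simultaneously. Everything in this package is organized around 10-s trials
sampled at 1000 Hz, positions in cm in screen-centered coordinates
(+x right, +y up). At the conventional 57-cm viewing distance 1 cm on the
screen subtends about 1 degree of visual angle; the package documents but
never enforces this equivalence.

The target is a sum of sinusoids per axis — a fundamental plus one second
or third harmonic:

$$x(t) = A_{1x}\cos\omega t + A_{2x}\cos(h_x\omega t - \varphi_x), \qquad
  y(t) = A_{1y}\sin\omega t + A_{2y}\sin(h_y\omega t - \varphi_y),$$

with $\omega = 2\pi/5$ rad/s, so one revolution of the figure takes 5 s and
a 10-s trial traverses it twice. This construction produces paths that look
unpredictable to the participant while keeping velocity and direction
smooth. The five packaged parameter sets (`load_pattern_table()`) live in a
single human-readable CSV (`inst/extdata/target_patterns.csv`) so they can
be corrected or extended without touching code; phases are stored in
degrees, as printed, and converted to radians at load. All five patterns
share, by design, a path length near 160 cm per trial and a mean tangential
speed near 16 cm/s; the package verifies both within 5% in its tests.
Sampling evaluates the closed form at each time stamp — the trajectory is
analytic, so no integration is involved.

## The generative model of behavior

The simulator exists so that every metric and every group-level statistic
can be exercised, with known ground truth, on data of realistic scale and
difficulty. It is deliberately the *simplest* generative model consistent
with the measured quantities.

### Hand

The cursor is modeled as

$$\mathrm{cursor}(t) = S[\mathrm{target}](t - \tau_h) + \varepsilon(t),$$

where $\tau_h$ is the configurable visuomotor delay (`hand_lag_ms`, default
49 ms), $S$ is a zero-phase 2nd-order Butterworth low-pass (default 1.5 Hz,
matching the 0–2 Hz band in which visuomotor feedback corrections operate),
and $\varepsilon$ is additive Gaussian positional noise. Because $S$ is
zero-phase, the *whole* temporal lag is carried by $\tau_h$: the
cross-correlation estimator recovers the configured delay exactly in the
noise-free case, which is the anchor for all parameter-recovery tests. The
price is that the smoothed reference is formally acausal within the
filter's support; the pure-delay contract (cursor depends only on the
target up to $t-\tau_h$) is therefore stated and tested with smoothing
disabled, and holds up to the symmetric kernel width otherwise.

The noise has two bands, because a single band cannot reproduce the human
numbers: a slow **drift** (default SD 1.0 cm per axis, band 0.1 Hz) that
produces spatial error with almost no velocity, and a **tremor** band
(default SD 0.5 cm, 5.5 Hz) that produces the velocity fluctuations and the
submovement intermittency. With these defaults a simulated "male-default"
trial shows a cursor–target distance near 1.6 cm, a residual (lag-
compensated) distance near 1.5 cm, a mean tangential velocity near 19 cm/s
with SD near 9 cm/s, about 60 submovements per trial, and peak
cross-correlations near 0.97 — the scale of the corresponding human group
means. Noise is synthesized spectrally (white Gaussian spectrum shaped by
the squared Butterworth magnitude response, DC removed), which is exactly
stationary and free of filter edge transients.

The cursor is held at its start position until `onset_latency_ms` (default
325 ms) and then joins the moving reference with a minimum-jerk catch-up
blend (default 300 ms), so the speed threshold that defines measured onset
latency (10 cm/s) is crossed at the configured time.

### Gaze

Between saccades, gaze integrates the delayed target velocity with a
pursuit gain $g$ (`sp_gain`, default 0.80): with $g<1$ the position error
grows at $(1-g)\cdot 16\ \mathrm{cm/s}\approx 3.2$ cm/s along the path.
When the error exceeds `saccade_threshold_cm` (default 0.6 cm) a
**predictive catch-up saccade** of `saccade_duration_ms` (30 ms,
minimum-jerk profile) corrects the full error and lands *ahead* of the
delayed target along its direction of motion, by
$(\texttt{saccade\_correction}-1)\times|\mathrm{error}|$ (default 0.95
error widths, i.e. `saccade_correction = 1.95`). Landing ahead makes the
error sawtooth oscillate symmetrically around zero; saccades that merely
undershoot toward the target would leave the eye on average *behind* it,
and the measured eye–target lag would then exceed the configured delay by
half the drift (tens of ms). The overshoot constant was calibrated so the
recovered lag is unbiased to about 1 ms; with the default threshold the
model produces ≈2.7 catch-up saccades per second, matching human rates at
these gains. A small 1-Hz-band gaze noise (SD 0.75 cm) brings the
eye–target distance to the human scale (≈1.4 cm).

### Cohorts

`simulate_cohort()` draws per-participant parameters from sex-specific
Gaussians truncated to valid ranges (delays ≥ 5 ms, gain in (0, 1], noise
positive). Group means default to the published sex profile — hand lag
71 vs 49 ms, eye lag 60 vs 58 ms, pursuit gain 0.82 vs 0.80 for female vs
male groups, *identical* motor-noise distributions — encoding the
substantive hypothesis that the sex difference in tracking is temporal, not
spatial or oculomotor. Between-participant SDs default to the published
group SDs (lag 25/21 ms; residual-scale noise SD 0.27/0.22 cm; gain
0.09/0.08). Two latent factors couple eye and hand within a participant
(correlation `eye_hand_rho`, default 0.5): one links the two visuomotor
delays, one links hand noise with gaze noise and saccade threshold. This is
what makes the within-group eye–hand accuracy correlation emerge while the
groups stay offset in the hand metrics.

Each participant performs 10 trials with a randomized, counterbalanced
pattern order (each of the five patterns twice). Seeding is two-level: all
participant-level draws come from one stream seeded with the master seed;
each trial then uses the deterministic sub-seed
`trial_seed(master, participant, trial)`, so any single trial can be
re-simulated in isolation.

## Metric definitions and estimators

**Distance.** Mean per-sample Euclidean cursor–target distance.

**Lag.** The x and y signals of the two series are interleaved
(x₁,y₁,x₂,y₂,…) and the Pearson correlation of the interleaved sequences is
evaluated at every whole-sample shift of the original series (so x aligns
with x and y with y), truncated to the valid overlap, never wrapped; the
reported lag maximizes that correlation, at the native 1-ms resolution and
bounded to ±500 ms (wrapping or an unbounded search could alias the lag
onto the 5-s pattern period). Since Pearson correlation ignores sample
order, the interleaved correlation equals the correlation of the pooled
per-axis overlaps; the implementation computes all shifts exactly via FFT
cross-products and prefix sums, and the test suite proves it identical to a
brute-force per-shift loop.

**Residual distance.** Distance recomputed after shifting the cursor back
by the estimated lag, over the remaining overlap — the spatial error that
remains once the temporal error is removed.

**Velocity, submovements, onset.** Positions are zero-phase low-pass
filtered (default 10 Hz) and differentiated by central differences; the
tangential velocity is the speed of that vector. Submovements are counted
as sign changes of the tangential acceleration divided by two (each
submovement being one acceleration plus one deceleration phase), with a
hysteresis dead-band of 2% of the trial's peak acceleration so noise around
zero does not inflate the count (`deadband = 0` restores the literal rule);
an odd trailing crossing counts as a partial submovement, so an isolated
point-to-point reach counts as one. Onset latency is the first upward
crossing of 10 cm/s.

**Spectra.** Mean-removed one-sided periodogram aggregated onto 18 bins
centered at 0.11k Hz (k = 1…18). Bin values are mean densities, so
`sum(power) × 0.11` recovers the variance of a band-limited signal
(checked to 5%); a full 10-s trial is required to resolve the 0.11-Hz
spacing. A target axis with harmonic h shows energy exactly in the bins
containing 0.2 Hz and 0.2·h Hz.

**Approximate entropy.** Standard ApEn, $\Phi_m(r)-\Phi_{m+1}(r)$ with
Chebyshev template matching and self-matches. The source study does not
state its settings, so the package declares field-standard ones: m = 2,
r = 0.2 × SD of the analyzed signal, computed per axis on position
decimated to 100 Hz (the statistic is O(N²)); all three are parameters.
ApEn is invariant under joint rescaling of signal and tolerance, equals
zero for constant signals, and the implementation is tested to 1e-10
against a brute-force double loop.

**Saccades.** The original detection procedure is described elsewhere, so
the detector here is a declared stand-in: a velocity-threshold scheme
(peak > 40 cm/s for ≥ 6 ms, extended to the nearest local speed minimum or
10 cm/s crossing within 25 ms, merged below 20-ms gaps, minimum amplitude
0.3 cm), all constants configurable. Candidates touching the first or last
50 ms are discarded because velocity estimates there are one-sided.
Smooth-pursuit gain is the ratio of mean gaze speed to mean target speed
over desaccaded samples (intervals ± a 10-ms guard removed); the ratio of
means is robust to near-zero target-speed samples, where a mean of ratios
would explode. Eye–target distance and lag use the raw gaze signal,
saccades included — no desaccading distinction is drawn for those two
metrics.

## Statistics

Group comparisons use Student's pooled-variance t (the published degrees of
freedom, n₁+n₂−2, identify the pooled rather than the Welch test), two-
sided, with Cohen's d on the (n−1)-weighted pooled SD — at equal n this
reduces to $\sqrt{(s_1^2+s_2^2)/2}$. Summary-statistic entry points exist
for every test so printed worked examples are checkable without raw data;
note that from 2-d.p.-rounded summary inputs the recomputed d can differ
from a published value by up to ±0.01. Spectra and trial-course effects use
the classical mixed-design (split-plot) ANOVA: the between-subject effect
is tested against the subject-within-group stratum, the within effect and
interaction against the within-subject error; the decomposition is exact
(total SS equals the sum of components) and its type-I error is verified at
the nominal 5% by null simulation. No multiple-testing correction is
applied, matching the source analysis (α = 0.05 throughout). Age matching
removes the oldest member of the older group and the youngest of the
younger group in alternation until the mean gap is below 0.5 y (tolerance
and cap configurable), deterministically, with ties broken by participant
id.

## Analysis windows and numerical choices

- **Start trim.** By default every metric uses the full trial. The
  simulator's onset hold and catch-up make the first few hundred ms
  unrepresentative of steady-state tracking, and a lag estimated on a
  window that starts there is biased high by 1–4 ms; the recovery analyses
  in the tests therefore set `start_trim_s = 2`, leaving an 8-s
  steady-state window on which the estimator is empirically unbiased
  (±0.3 ms). The binned spectrum and the onset latency always use the full
  trial — the former needs the full duration to resolve its grid, the
  latter is defined by the pre-onset portion.
- **Filtering.** All smoothing is zero-phase (forward–backward 2nd-order
  Butterworth), applied over odd-reflection padding, with the filter state
  initialized at the signal's first value so constant signals pass without
  transients. Filter coefficients come from `signal::butter`; the
  filtering itself runs through `stats::filter` for speed.
- **Ties.** If two shifts tie in correlation (possible only on degenerate
  inputs), the smaller absolute lag wins.
- **Degenerate inputs.** Constant series are rejected where a correlation
  is undefined; all-zero speed yields an absent onset; an empty saccade
  table yields rate 0.

## Problem sizes used in the tests

Unit tests run on single trials or small cohorts (e.g. 3+3 participants at
250 Hz for the pipeline round-trip). The cohort-level acceptance checks use
the study's own conditions — 25+25 participants × 10 trials × 10 s at
1000 Hz — across 100 replicate cohorts for the recovery/power checks and
100 replicates for the ANOVA null; these sizes balance Monte-Carlo
precision (binomial SE ≈ 2–5% on a rate) against runtime.

## What the simulation does and does not show

The generator reproduces the *summary statistics* of human tracking (group
means and SDs of distance, lag, residual, velocity statistics, saccade rate,
pursuit gain) and the structural claims built on them. It does not attempt
waveform realism: no biomechanical arm or joystick dynamics, no learning
across trials, no blink artifacts, no main-sequence constraints on
saccades, and the within-trial noise spectrum is calibrated only to the
published summary statistics — the source data's noise spectrum is unknown.
Passing recovery tests therefore shows the estimators are correct and the
pipeline coherent under a plausible generative model; it does not validate
the generative model itself against raw human recordings.

One power limitation is worth stating explicitly, because it is a property
of the published numbers rather than of this implementation: with group
effect sizes like d ≈ 0.7 for the raw distance at n = 25 per group, a
two-sided α = 0.05 test detects the difference in at most ~66% of replicate
cohorts — and in a generator where the distance gap is purely lag-mediated
(equal spatial noise across groups, as the residual-error result demands)
the realized rate is nearer 50%. The temporal-lag difference (d ≈ 1.0)
reaches ~90%. Replicate-level expectations above those ceilings are not
attainable by any faithful simulation of those conditions.
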