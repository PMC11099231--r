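---
title: "Modeling distractor effects on categorical decisions: diffusion modeling and single-trial EEG decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling distractor effects on categorical decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftdecode)
```

## The scientific problem

When people categorize a stimulus — is this animal a dog or a bird? —
task-irrelevant input from the same or another sensory modality can
modulate the decision. Two broad hypotheses locate that modulation at
different processing stages: an *early* (sensory-encoding) account, in
which irrelevant evidence mixes into perceptual processing, and a
*late* (post-sensory decision) account, in which modality-specific
evidence is combined only at response formation. driftdecode implements
an analysis pipeline that addresses this question on two fronts at
once:

1. **Cognitive level.** Choices and reaction times are fitted with a
   hierarchical Bayesian drift-diffusion model (DDM), whose parameters
   dissociate the speed of evidence accumulation (drift rate `v`, a
   sensory-processing quantity), response caution (boundary separation
   `a`, a post-sensory quantity), response bias (starting point `z`)
   and non-decision time (`t`).
2. **Neural level.** Stimulus-locked EEG epochs are decoded trial by
   trial inside short sliding windows, asking *when* the brain
   represents distractor and no-distractor contexts differently, and
   *with which scalp topography*.

The experimental design the pipeline emulates has three conditions per
task — ND (no distractor), AD (auditory distractor), VD (visual
distractor) — run in blocks with ND always first. The defaults follow
that design: 60 ND and 120 trials in each distractor condition. In the
auditory task the stimulus is a rapid sequence of six 250 ms sounds
separated by 50 ms silences (1,750 ms total), and the reaction-time
clock starts at the target's onset within the sequence.

## The diffusion model and its likelihood

A single trial is modeled as a Wiener process with unit diffusion
coefficient starting at `z * a` (relative start `z` in (0, 1)), drifting
at rate `v` between absorbing boundaries 0 and `a`. The response is
given by the boundary reached first, the reaction time by the first
passage plus the non-decision time `t`. The trial likelihood is the
Wiener first-passage-time (WFPT) density, computed by a dual series
expansion — a small-time and a large-time representation with automatic
selection of whichever needs fewer terms at the requested truncation
tolerance (`err_tol = 1e-7`). Two invariants anchor the implementation
and are tested continuously: the two boundary densities integrate to
one, and the upper-boundary mass equals the gambler's-ruin closed form
`(1 - exp(-2vw)) / (1 - exp(-2va))` with `w = z a`.

Responses are stimulus-coded: the upper boundary is the "bird"
response. Each generated trial carries a target category; on
dog-target trials the drift sign is flipped, so a single positive `v`
per condition measures evidence toward the *correct* category while
`z` captures an overall bird/dog response bias (0.5 = none). During
fitting the target is recovered from `choice` and `correct`, so no
extra column is required of user data.

The package also includes an Euler–Maruyama first-passage simulator
(`simulate_ddm`, default step 0.1 ms). It is deliberately a separate
code path from the series density: the two validate each other in the
test suite (density vs. simulation histogram; simulated boundary
fractions vs. the closed form), and the simulator doubles as the
behavioral data generator.

## Hierarchical estimation

`fit_hddm()` estimates subject-level DDM parameters drawn from
group-level Gaussian distributions. The model space crosses which of
`v`, `a`, `t` may vary by condition: eight variants, numbered 1 (all
fixed) through 8 (all varying), with `z` always shared across
conditions within subject. Priors on group means are weakly
informative — `v`: N(2, 3²); `a`: N(1.5, 0.75²) truncated above 0.3;
`t`: N(0.4, 0.2²) truncated at 0; logit `z`: N(0, 1) — with
half-normal(1) priors on the group SDs (one per base parameter, shared
across conditions; per-condition SDs would be poorly identified at the
group sizes this package targets).

The sampler is an adaptive Metropolis-within-Gibbs scheme:

- group means: conjugate Gibbs draws (truncated-normal where the prior
  is truncated);
- group SDs: random-walk Metropolis on the log scale;
- subject-level parameters: componentwise random-walk Metropolis with
  Robbins–Monro step-size adaptation toward 44% acceptance during
  burn-in, frozen afterwards so the kept draws form a valid chain;
- an interweaved non-centered pass per iteration that re-proposes each
  group SD and mean while holding the *standardized* subject effects
  fixed. This ancillarity–sufficiency interweaving step is what lets
  the chains mix when the between-subject SD collapses toward zero —
  exactly the regime of synthetic data generated with identical
  subjects, where the centered parameterization alone funnels badly.

Support constraints (`a > 0`, `t >= 0`, `t` below every observed RT)
are enforced through the likelihood, which returns zero density for
invalid proposals; the group-level Gaussians stay untruncated so the
Gibbs steps remain exactly conjugate.

Convergence is monitored with split-R̂ (`gelman_rubin()`): each chain is
halved and the usual between/within variance ratio computed across the
segments; values at or below 1.1 are treated as acceptable. Model
comparison uses the conditional DIC on subject-level parameters,
`DIC = D̄ + pD`, with the deviance trace recorded during sampling and
`pD = D̄ − D(θ̄)` evaluated at the posterior mean; a margin of 10 is
read as a decisive preference. Directional hypotheses about group
means are expressed as posterior probabilities
(`posterior_prob_greater`), with `p < 0.05` or `p > 0.95` the
conventional significance reading.

Two chains are the default: the study this emulates does not report a
chain count, and two is the minimum for R̂.

## Single-trial EEG discrimination

For each sliding window (60 ms wide, stepped every 10 ms, centers from
−100 to 900 ms — 101 windows), a ridge-regularized logistic regression
learns a channel weighting `w` whose output `y = w'x + b` is oriented
positive for no-distractor and negative for distractor trials. Each
trial is scored by a discriminator trained on all *other* trials
(leave-one-trial-out), and the window's discrimination performance is
the ROC area (Az) of those held-out scores — 0.5 is chance. Rather than
assuming 0.5, a per-window significance threshold is estimated by
recomputing the cross-validated Az under label permutations (1,000 by
default) and taking the 95th percentile of the null.

Three implementation choices deserve comment:

- **Featurization.** Samples inside a window enter as their per-channel
  mean (`feature_mode = "window_mean"`); the alternative, every sample
  as its own feature, is available behind the flag. The mean is the
  more robust choice at the trial counts this design produces.
- **Regularization.** A small L2 penalty (`l2_lambda = 1e-3`) keeps the
  98-channel fit defined when trials are few; at `lambda -> 0` the fit
  agrees with an unpenalized IRLS solution to four decimals (tested).
- **LOO bias.** Under the null, leave-one-out Az sits slightly *below*
  0.5 (about 0.48 at 100 trials): removing a trial tilts its training
  set against that trial's class. This well-known pessimistic bias is
  one more reason to calibrate significance against the permutation
  null, which carries the same bias, instead of against 0.5.

The scalp expression of each window's component is its forward model
`a = X'y / (y'y)` — the normalized covariance between the discriminant
output and each channel — which is interpretable as a topography where
the discriminant weights themselves are not. Peak latencies inside a
component window are the window centers of maximal Az (ties break
early), and the component amplitude separation is the difference of
mean held-out `y` between distractor and no-distractor trials, negative
by construction under the sign convention.

For the permutation null, a fast mode replaces the full leave-one-out
loop by stratified 10-fold cross-validation, making 100+ permutations
practical on a desktop; the full LOO null remains the default mode.

## Temporal components and group inference

Windows with similar topographies are grouped by k-means (Euclidean
metric, 10 seeded restarts) on the forward-model vectors, with the
number of clusters chosen by maximal mean silhouette over k = 2..6.
Maximal runs of a common cluster label along the window grid define the
temporal components; transition points fall midway between adjacent
runs.

Two practical points about what enters the clustering:

- **Normalization.** Forward models are scaled to unit norm by default
  (`normalize = TRUE`). A component's forward-model *magnitude* waxes
  and wanes with its time course — for the synthetic raised-cosine
  components it ramps several-fold inside one window — while its
  *direction* is the scalp pattern proper. Raw-Euclidean k-means on
  such data splits one component into strong/weak sub-clusters;
  normalized clustering answers the intended question, "which windows
  share a topography". Raw intensities remain available via
  `normalize = FALSE`, and both choices are exercised in the tests.
- **Which windows.** Clustering is meant for periods of *persistent*
  significant discrimination. Because adjacent windows overlap (60 ms
  width on a 10 ms grid), a single false-positive window smears across
  up to `width/step = 6` neighbors, and such short runs carry coherent
  noise topographies that can masquerade as a component. Selecting
  windows in significant runs longer than one window span (at least 7
  adjacent centers) removes them; `find_clusters()` implements the run
  logic.

Group-level comparison of two Az traces (e.g. AD−ND vs. VD−ND
decoding) uses a percentile bootstrap over subjects: the paired mean
difference per window, 1,000 resamples, and a [2.5, 97.5] percentile
interval; a window is significant when the interval excludes zero (each
bound a 2.5% one-sided test). To control multiple comparisons across
windows, significant windows must form contiguous clusters of a minimum
length: the 95th percentile of a null distribution of maximum cluster
sizes, obtained by shuffling the temporal order of windows (jointly
across subjects, preserving each subject-window difference), floored at
3 consecutive windows (30 ms on the 10 ms grid). For each surviving
cluster, the participant-consistency proportion — the fraction of
subjects whose mean difference over the cluster shares the group sign —
guards against effects driven by a minority.

The bootstrap statistic is the mean paired difference; a median option
exists (`stat = "median"`) for heavy-tailed Az distributions. The
cluster criterion is computed per comparison.

## The synthetic generator

Because the pipeline's correctness cannot be demonstrated on data it
was tuned to, every stage is exercised on synthetic data whose ground
truth is known:

- **Design.** `make_trial_schedule()` reproduces the blocked structure
  (ND first, AD/VD order randomized by seed), uniform target positions,
  balanced congruency within distractor blocks, and sequence-timing
  onsets for the auditory task. Trial counts are explicit parameters
  with defaults (60, 120, 120) — the emulated design's printed total of
  240 conflicts with its per-condition counts, so the generator never
  hard-codes a total.
- **Behavior.** `simulate_behavior()` draws choices and RTs from the
  DDM itself via the Euler–Maruyama simulator, per-condition
  parameters.
- **EEG.** `simulate_epochs()` adds, on distractor trials only, a
  raised-cosine bump (a smooth, compactly supported time course; the
  emulated study never specifies a waveform) on a unit-norm topography,
  on top of white or AR(1) background noise. By default the early
  window (190–370 ms) component attaches to AD trials and the late
  (520–630 ms) to VD trials, mirroring the finding the design targets;
  the mapping is configurable and is a fixture choice, not a claim.
  Congruency is generated and stored but has no generative effect.
- **Continuous recordings.** `make_continuous_recording()` produces
  noise with event markers to exercise epoching.

The default synthetic montage is 32 channels at 250 Hz — enough spatial
and temporal structure for every statistical property at desk scale;
a 98-of-128-channel, 1,000 Hz configuration mirroring the emulated
recordings is reachable through the config. What the generator does
*not* emulate: volume conduction from realistic sources, eye/muscle
artifacts, autocorrelated inter-trial dependencies, or behavioral-EEG
coupling beyond condition labels. Passing tests therefore demonstrate
the *statistics* are calibrated and the *recovery* works when the
model family is true — not that the pipeline is robust to every
real-data pathology.

## Preprocessing

The deterministic chain select channels → average reference → 0.5–40 Hz
fourth-order Butterworth band-pass → epoch → amplitude rejection
mirrors standard practice. Filtering is zero-phase (forward–backward),
which doubles the effective order; epochs span the half-open window
[−200, 1000) ms so 1,200 ms is exactly 1,200 samples at 1 kHz;
rejection is strict at ±120 μV. Bad channels are interpolated by
inverse-distance weighting of the 4 nearest good sensors — simpler than
spherical splines and adequate at desk scale — with a warning above the
5% bad-channel ceiling. ICA-based artifact removal is deliberately not
reimplemented; externally cleaned epochs enter through the same
container.

## File formats and determinism

Trial tables are UTF-8 CSV; configs are YAML (JSON accepted) with
unknown keys rejected; stage outputs are JSON. Epoch sets use the
package's own single-file container: a magic line, one JSON header line
(dimensions, channel names, time axis, labels, sampling rate,
provenance), then the tensor as little-endian float64 — exactly
round-trippable and trivially readable from any language. Milliseconds
are the I/O time unit everywhere; the DDM core works in seconds, with
the conversion at the trial-table boundary. Sample indices follow R's
1-based convention. Every stochastic stage takes an explicit seed and
records it in its output; identical config and seed reproduce outputs
byte for byte (tested).

## Problem sizes in the test suite

The test suite exercises every property at sizes chosen to make each
check statistically meaningful in seconds-to-minutes: decoder
calibration on 8–20 seeded epoch sets of 100 trials × 32 channels;
type-I calibration of the permutation threshold on 40–100 null
datasets at a single window; hierarchical fits on 6–10 subjects with
60–100 trials per condition and 900–2,000 draws; the DIC
model-recovery contrast on 8–20 subjects. The acceptance script
(`scripts/acceptance.R`) runs the larger end of these ranges; the unit
suite the smaller. Recovery tolerances (10% bias on group means, one
grid step on latencies, ±0.03 on null Az) are fixed properties of the
method at those sizes, not tuned values.

## Known limitations

- No inter-trial variability parameters (sv, st, sz): the 4-parameter
  DDM is the modeled family.
- The conditional DIC is reported; fully marginalized alternatives
  (WAIC, LOO-CV on the hierarchical likelihood) are out of scope.
- The decoder is linear; nonlinear decoders and source localization are
  non-goals.
- Percentile bootstrap intervals are slightly anticonservative at small
  subject counts; the cluster criterion compensates at the level of
  temporal extent, not per-window rate.
- k-means with silhouette selection cannot select k = 1; a single
  uniform topography regime will still be split into two clusters, so
  the component report should be read jointly with the Az trace.
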