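# driftdecode

An R package for studying how task-irrelevant distractors modulate
categorical decision-making, at two levels jointly:

- **Cognitive level** — hierarchical Bayesian drift-diffusion modeling
  (DDM) of choice/RT data: Wiener first-passage-time likelihood, an
  eight-variant model space crossing which of drift rate *v*, boundary
  separation *a* and non-decision time *t* vary by condition, adaptive
  Metropolis-within-Gibbs sampling with interweaving, DIC model
  comparison, split-R̂ convergence diagnostics, and directional
  posterior probabilities.
- **Neural level** — single-trial sliding-window EEG decoding: a
  ridge-logistic discriminator per 60 ms window (10 ms steps, centers
  −100..900 ms) with leave-one-trial-out Az, permutation-derived
  significance thresholds, forward-model scalp topographies
  `a = X'y / (y'y)`, k-means + silhouette temporal clustering of
  topographies into components, and cluster-based percentile-bootstrap
  group statistics with a data-driven minimum cluster criterion and
  participant-consistency proportions.

The experimental design it targets has three conditions per task — ND
(no distractor), AD (auditory distractor), VD (visual distractor) — and
the package ships a first-class synthetic generator for that design
(blocked schedules, DDM-governed behavior, EEG epochs with planted
condition-discriminative components), so the full pipeline is testable
end to end with known ground truth. Standard EEG preprocessing
(channel selection, average reference, 0.5–40 Hz zero-phase
Butterworth, epoching, ±120 μV rejection, bad-channel interpolation)
is included.

## The model in brief

A trial is a Wiener process with unit diffusion starting at `z·a`,
drifting at `v` between absorbing boundaries 0 and `a`; the boundary
reached first gives the choice ("bird" at the top, "dog" at the
bottom), the first-passage time plus `t` gives the RT. The likelihood
is the WFPT density (dual series expansion, truncation tolerance
1e-7). Subject parameters are drawn from group-level Gaussians;
comparing where condition differences are allowed (in *v*, *a*, *t*)
localizes a distractor's effect to sensory processing (drift),
post-sensory caution (boundary), or neither. The decoder asks the same
question of the EEG: *when* (which windows) and *where* (which
topographies) distractor and no-distractor trials are represented
differently, with Az = 0.5 as chance and significance calibrated
against permutation nulls rather than assumed.

## Worked example

Simulate six subjects of the blocked design (drift slowed by both
distractor types), filter, summarise, and fit the drift-varying model:

```r
library(driftdecode)
library(dplyr)

design <- design_spec(n_nd = 60, n_ad = 120, n_vd = 120)
params <- list(ND = ddm_params(v = 2.0, a = 1.4, z = 0.5, t = 0.3),
               AD = ddm_params(v = 1.5, a = 1.4, z = 0.5, t = 0.3),
               VD = ddm_params(v = 1.5, a = 1.4, z = 0.5, t = 0.3))
trials <- bind_rows(lapply(1:6, function(s)
  simulate_behavior(
    make_trial_schedule(design, "visual", seed = 100 + s,
                        subject_id = sprintf("S%02d", s)),
    params, seed = 200 + s)))

trials <- trials |> filter_premature() |> trim_rt_tails(0.05)
condition_summaries(trials)
#> # A tibble: 3 × 7
#>   task   condition n_subjects mean_acc sd_acc mean_rt_ms sd_rt_ms
#>   <chr>  <chr>          <int>    <dbl>  <dbl>      <dbl>    <dbl>
#> 1 visual AD                 6    0.890 0.0114       638.     11.4
#> 2 visual ND                 6    0.926 0.0251       609.     25.1
#> 3 visual VD                 6    0.911 0.0153       625.     12.3

fit <- fit_hddm(trials, ddm_model_spec(2), n_samples = 1500,
                n_burn = 500, n_chains = 2, seed = 3)
tidy(fit) |> filter(grepl("^mu_v", term))
#> # A tibble: 3 × 6
#>   term    estimate std.error conf.low conf.high  rhat
#>   <chr>      <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#> 1 mu_v_AD     1.66    0.0755     1.51      1.80  1.00
#> 2 mu_v_ND     2.02    0.123      1.78      2.26  1.00
#> 3 mu_v_VD     1.83    0.0810     1.66      1.98  1.01
```

The group drift posteriors recover the generative ordering (ND fastest
at 2.0; both distractor conditions near 1.5, pulled slightly together
by hierarchical shrinkage at six subjects), with mean accuracy and RT
per condition aggregated subject-first. `max(gelman_rubin(fit))` here
is 1.008 — comfortably under the 1.1 convergence ceiling — and
`dic(fit)` compares model variants (lower is better, a margin of 10 is
decisive).

Decoding synthetic epochs with an early planted component on the
distractor trials:

```r
set.seed(7)
early <- component_spec(c(190, 370), rnorm(32), amplitude = 1.2, noise_sd = 1)
late  <- component_spec(c(520, 630), rnorm(32), amplitude = 0, noise_sd = 1)
sched <- make_trial_schedule(design_spec(60, 60, 60), "visual", seed = 8)
sched <- sched[sched$condition %in% c("ND", "AD"), ]
epochs <- simulate_epochs(sched, early, late, sfreq_hz = 250, seed = 9)

res <- loo_discriminant(epochs)
res
#> <discriminator_result> 101 windows (-100..900 ms), 120 trials (ND vs AD)
#> peak Az 1.000 at 300 ms
peak_latency(res, c(190, 370))
#> [1] 300
```

The discrimination peak lands inside the planted 190–370 ms window;
`autoplot(res)` draws the Az time course, and
`cluster_topographies(res$forward_models, res$window_centers_ms)`
segments the forward models into temporal components.

A command-line interface over the same functions is available through
`run_cli()` (subcommands `simulate`, `fit-ddm`, `decode`, `cluster`,
`group`, `report`) or the wrapper script `inst/cli/driftdecode.R`.

## Package layout

- `R/` — trial tables and containers (`read_trial_table`,
  `read_epochs`), configuration (`read_config`), synthetic generation
  (`make_trial_schedule`, `simulate_behavior`, `simulate_epochs`),
  behavioral filters (`filter_premature`, `trim_rt_sd`,
  `trim_rt_tails`, `condition_summaries`), DDM core (`wfpt_density`,
  `simulate_ddm`, `ddm_loglik`), hierarchical fitting (`fit_hddm`,
  `dic`, `compare_ddm_models`, `gelman_rubin`,
  `posterior_prob_greater`), preprocessing, decoding
  (`loo_discriminant`, `permutation_threshold`, `forward_model`), and
  group inference (`cluster_topographies`, `bootstrap_az_difference`,
  `max_cluster_null`, `find_clusters`, `participant_consistency`).
- `src/` — the WFPT density, diffusion simulator and ridge-logistic
  IRLS/LOO loops in C++ (Rcpp/RcppArmadillo).
- `vignettes/distractor-pipeline.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical conventions, limitations.
- `tests/testthat/` — oracle-based unit tests and property suites.
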