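# shared fixture builders; everything is generated in code at test time

default_params3 <- function(v = c(1.5, 1.5, 1.5), a = 1.4, z = 0.5,
                            t = 0.3) {
  list(ND = ddm_params(v[1], a, z, t),
       AD = ddm_params(v[2], a, z, t),
       VD = ddm_params(v[3], a, z, t))
}

# one subject's simulated behavior with n trials per condition
gen_subject_trials <- function(sid, seed, n_per_cond = 50,
                               params = default_params3(), dt = 1e-4) {
  d <- design_spec(n_per_cond, n_per_cond, n_per_cond)
  sch <- make_trial_schedule(d, "visual", seed = seed, subject_id = sid)
  simulate_behavior(sch, params, seed = seed + 1L, dt = dt)
}

gen_group_trials <- function(n_subjects, n_per_cond = 50,
                             params = default_params3(), seed0 = 100,
                             dt = 1e-4) {
  dplyr::bind_rows(lapply(seq_len(n_subjects), function(s) {
    gen_subject_trials(sprintf("S%02d", s), seed0 * s,
                       n_per_cond = n_per_cond, params = params, dt = dt)
  }))
}

# pure-noise epoch set with balanced two-class labels
noise_epochs <- function(n_trials = 100, n_channels = 16,
                         sfreq_hz = 250, seed = 1,
                         labels = rep(c("ND", "AD"),
                                      length.out = n_trials)) {
  set.seed(seed)
  n_samples <- length(seq(-200, 1000 - 1000 / sfreq_hz,
                          by = 1000 / sfreq_hz))
  epoch_set(array(rnorm(n_trials * n_channels * n_samples),
                  dim = c(n_trials, n_channels, n_samples)),
            times_ms = seq(-200, by = 1000 / sfreq_hz,
                           length.out = n_samples),
            labels = labels, sfreq_hz = sfreq_hz)
}

# epochs with a planted early (and optionally late) component on the
# distractor class
planted_epochs <- function(n_per_class = 40, n_channels = 16,
                           sfreq_hz = 250, seed = 1, amp_early = 2,
                           amp_late = 0, window_early = c(190, 370),
                           window_late = c(520, 630),
                           late_condition = "AD") {
  set.seed(seed + 5000)
  topoA <- rnorm(n_channels)
  topoB <- rnorm(n_channels)
  topoB <- topoB - topoA * sum(topoA * topoB) / sum(topoA^2) # orthogonal
  sch <- tibble::tibble(
    subject_id = "S01", task = "visual",
    condition = rep(c("ND", "AD"), each = n_per_class),
    congruency = rep(c("none", "congruent"), each = n_per_class),
    target_onset_ms = 0, rt_ms = NA_real_, choice = NA_character_,
    correct = NA, target = "dog"
  )
  early <- component_spec(window_early, topoA, amplitude = amp_early,
                          noise_sd = 1)
  late <- component_spec(window_late, topoB, amplitude = amp_late,
                         noise_sd = 1)
  simulate_epochs(sch, early, late, sfreq_hz = sfreq_hz, seed = seed,
                  assign = list(early = "AD", late = late_condition))
}

# minimal behavioral table with given RTs (choices all "dog", correct)
make_rt_table <- function(rt_ms, sid = "S01") {
  n <- length(rt_ms)
  tibble::tibble(
    subject_id = sid, task = "visual",
    condition = rep(c("ND", "AD"), length.out = n),
    congruency = rep(c("none", "congruent"), length.out = n),
    target_onset_ms = 0, rt_ms = rt_ms,
    choice = rep("dog", n), correct = TRUE)
}

# independent Euler-Maruyama first-passage oracle in plain R
em_oracle <- function(v, a, z, t0, n, dt = 1e-4, seed = 1) {
  set.seed(seed)
  x <- rep(z * a, n)
  steps <- integer(n)
  active <- seq_len(n)
  hit_upper <- logical(n)
  k <- 0L
  sdt <- sqrt(dt)
  while (length(active) > 0 && k < 60 / dt) {
    k <- k + 1L
    x[active] <- x[active] + v * dt + sdt * rnorm(length(active))
    done_up <- active[x[active] >= a]
    done_lo <- active[x[active] <= 0]
    hit_upper[done_up] <- TRUE
    steps[c(done_up, done_lo)] <- k
    active <- setdiff(active, c(done_up, done_lo))
  }
  data.frame(rt = t0 + steps * dt, upper = hit_upper)
}
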