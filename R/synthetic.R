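#' Experimental design specification
#'
#' Trial counts and sequence timing of the distractor design: three
#' conditions per task (ND no-distractor, AD auditory-distractor, VD
#' visual-distractor), the ND block run first to establish baseline
#' performance, and — for the auditory task — a rapid sequence of
#' `n_positions` sounds of `sound_dur_ms` each separated by `gap_ms`
#' silences. Defaults mirror the emulated study: 60 ND and 120 trials in
#' each distractor condition, six 250 ms sounds with 50 ms gaps.
#'
#' @param n_nd,n_ad,n_vd Trials per condition (>= 1).
#' @param sound_dur_ms Duration of each sound in the auditory sequence.
#' @param gap_ms Silent interval between sounds.
#' @param n_positions Number of sequence positions the target can occupy.
#' @param nd_first Run the ND block first (the emulated design always
#'   does).
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_nd = 60, n_ad = 120, n_vd = 120,
                        sound_dur_ms = 250, gap_ms = 50,
                        n_positions = 6, nd_first = TRUE) {
  if (any(c(n_nd, n_ad, n_vd) < 1)) {
    abort("each condition needs at least one trial",
          class = "driftdecode_design_error")
  }
  if (sound_dur_ms <= 0 || gap_ms < 0 || n_positions < 1) {
    abort("invalid sequence timing", class = "driftdecode_design_error")
  }
  structure(list(n_nd = as.integer(n_nd), n_ad = as.integer(n_ad),
                 n_vd = as.integer(n_vd), sound_dur_ms = sound_dur_ms,
                 gap_ms = gap_ms, n_positions = as.integer(n_positions),
                 nd_first = isTRUE(nd_first)),
            class = "design_spec")
}

#' Total duration of the auditory stimulus sequence
#'
#' `n_positions * sound_dur_ms + (n_positions - 1) * gap_ms`; with the
#' default six 250 ms sounds and 50 ms gaps this is 1,750 ms.
#'
#' @param design A [design_spec].
#' @return Duration in milliseconds.
#' @export
sequence_duration <- function(design) {
  design$n_positions * design$sound_dur_ms +
    (design$n_positions - 1) * design$gap_ms
}

#' Generate a blocked trial schedule
#'
#' Builds one subject's trial schedule: the ND block first (when
#' `nd_first`), then the AD and VD blocks in seed-randomized order.
#' Target sequence position is uniform over `n_positions`; congruency is
#' balanced within each distractor block (and `"none"` for ND); target
#' category (dog/bird) is balanced within block. For the auditory task
#' the target onset is `(position - 1) * (sound_dur_ms + gap_ms)`; for
#' the visual task all stimuli appear at once, so onset is 0.
#' `rt_ms`, `choice` and `correct` are left `NA` for
#' [simulate_behavior()].
#'
#' @param design A [design_spec].
#' @param task `"visual"` or `"auditory"`.
#' @param seed Integer seed (block order, positions, balancing).
#' @param subject_id Subject identifier for the `subject_id` column.
#' @return A [trial_table] tibble with an extra `target` column.
#' @export
make_trial_schedule <- function(design, task = c("visual", "auditory"),
                                seed = 1L, subject_id = "S01") {
  task <- match.arg(task)
  stopifnot(inherits(design, "design_spec"))
  set.seed(seed)

  soa <- design$sound_dur_ms + design$gap_ms
  block <- function(condition, n) {
    position <- sample.int(design$n_positions, n, replace = TRUE)
    congruency <- if (condition == "ND") {
      rep("none", n)
    } else {
      sample(rep(c("congruent", "incongruent"), length.out = n))
    }
    onset <- if (task == "auditory") (position - 1) * soa else rep(0, n)
    tibble::tibble(
      subject_id = subject_id,
      task = task,
      condition = condition,
      congruency = congruency,
      target_onset_ms = onset,
      rt_ms = NA_real_,
      choice = NA_character_,
      correct = NA,
      target = sample(rep(c("dog", "bird"), length.out = n))
    )
  }

  distractor_order <- sample(c("AD", "VD"))
  order_conditions <- if (design$nd_first) {
    c("ND", distractor_order)
  } else {
    sample(c("ND", distractor_order))
  }
  counts <- c(ND = design$n_nd, AD = design$n_ad, VD = design$n_vd)
  schedule <- dplyr::bind_rows(
    lapply(order_conditions, function(cond) block(cond, counts[[cond]]))
  )
  validate_trial_table(schedule)
}

#' Simulate choices and reaction times for a schedule
#'
#' Fills `rt_ms`, `choice` and `correct` by first-passage simulation of
#' the diffusion process with per-condition parameters. The upper
#' boundary maps to the "bird" response; on dog-target trials the
#' process is mirrored (equivalent to a sign-flipped drift), so `v` is
#' the rate of evidence toward the correct category and `z` a bias
#' toward "bird". All simulated `rt_ms` exceed `t * 1000`.
#'
#' @param schedule A [trial_table] with a `target` column.
#' @param params_by_condition Named list (`ND`, `AD`, `VD` as needed) of
#'   [ddm_params].
#' @param seed Integer seed.
#' @param dt Euler–Maruyama step in seconds.
#' @return The schedule with behavior filled in.
#' @export
simulate_behavior <- function(schedule, params_by_condition, seed = 1L,
                              dt = 1e-4) {
  schedule <- validate_trial_table(schedule)
  if (!"target" %in% names(schedule)) {
    abort("schedule needs a target column (see make_trial_schedule)",
          class = "driftdecode_design_error")
  }
  need <- unique(schedule$condition)
  missing_cond <- setdiff(need, names(params_by_condition))
  if (length(missing_cond) > 0) {
    abort(paste0("missing DDM parameters for condition(s): ",
                 paste(missing_cond, collapse = ", ")),
          class = "driftdecode_design_error")
  }
  set.seed(seed)
  rt_ms <- numeric(nrow(schedule))
  choice <- character(nrow(schedule))
  for (cond in need) {
    p <- as_ddm_params(params_by_condition[[cond]])
    for (tgt in c("bird", "dog")) {
      idx <- which(schedule$condition == cond & schedule$target == tgt)
      if (length(idx) == 0) next
      # mirror the process for dog targets: upper boundary = dog response
      zz <- if (tgt == "bird") p$z else 1 - p$z
      sim <- ddm_sim_cpp(length(idx), p$v, p$a, zz, p$t, dt)
      rt_ms[idx] <- sim[, 1] * 1000
      hit_upper <- sim[, 2] > 0
      choice[idx] <- if (tgt == "bird") {
        ifelse(hit_upper, "bird", "dog")
      } else {
        ifelse(hit_upper, "dog", "bird")
      }
    }
  }
  schedule$rt_ms <- rt_ms
  schedule$choice <- choice
  schedule$correct <- schedule$choice == schedule$target
  schedule
}

#' Planted EEG component specification
#'
#' Describes one condition-discriminative component to plant in
#' synthetic epochs: a time window, a unit-norm scalp topography, a
#' per-trial gain, and the background-noise model of the epoch set. The
#' component time course is a raised-cosine bump supported on the
#' window.
#'
#' @param window_ms Length-2 `[start, end]` in ms, `start < end`.
#' @param topography Numeric vector over channels; normalized to unit
#'   norm by the constructor.
#' @param amplitude Component gain on distractor trials (>= 0).
#' @param noise_sd Stationary noise standard deviation (> 0).
#' @param noise_model `"white"` or `"ar1"`.
#' @param ar1_coef Lag-1 coefficient in (-1, 1) for `"ar1"` noise.
#' @return A `component_spec` list.
#' @export
component_spec <- function(window_ms, topography, amplitude = 1,
                           noise_sd = 1, noise_model = c("white", "ar1"),
                           ar1_coef = 0.5) {
  noise_model <- match.arg(noise_model)
  if (length(window_ms) != 2 || window_ms[1] >= window_ms[2]) {
    abort("window_ms must be [start, end] with start < end",
          class = "driftdecode_design_error")
  }
  nrm <- sqrt(sum(topography^2))
  if (!is.finite(nrm) || nrm == 0) {
    abort("topography must be a nonzero vector",
          class = "driftdecode_design_error")
  }
  if (amplitude < 0 || noise_sd <= 0) {
    abort("amplitude must be >= 0 and noise_sd > 0",
          class = "driftdecode_design_error")
  }
  if (abs(ar1_coef) >= 1) {
    abort("ar1_coef must be in (-1, 1)", class = "driftdecode_design_error")
  }
  structure(list(window_ms = as.numeric(window_ms),
                 topography = topography / nrm,
                 amplitude = amplitude, noise_sd = noise_sd,
                 noise_model = noise_model, ar1_coef = ar1_coef),
            class = "component_spec")
}

raised_cosine <- function(times_ms, window_ms) {
  h <- numeric(length(times_ms))
  inside <- times_ms >= window_ms[1] & times_ms <= window_ms[2]
  phase <- (times_ms[inside] - window_ms[1]) / diff(window_ms)
  h[inside] <- 0.5 * (1 - cos(2 * pi * phase))
  h
}

#' Simulate stimulus-locked epochs with planted components
#'
#' Generates background noise on every trial (per the `early` spec's
#' noise settings) and adds `amplitude * topography %o% h(t)` on
#' distractor trials only, where `h` is a raised-cosine bump on the
#' component window. By default the early component is planted on AD
#' trials and the late component on VD trials, emulating a design in
#' which the auditory distractor modulates sensory processing and the
#' visual distractor the post-sensory decision stage; `assign` overrides
#' this mapping.
#'
#' @param schedule A [trial_table] (only `condition` is used).
#' @param early,late [component_spec] objects (same channel count).
#' @param sfreq_hz Sampling rate.
#' @param epoch_window_ms Half-open epoch window `[tmin, tmax)` in ms.
#' @param seed Integer seed.
#' @param assign Named list mapping `early`/`late` to the condition(s)
#'   that carry that component.
#' @return An [epoch_set] labeled by condition.
#' @export
simulate_epochs <- function(schedule, early, late, sfreq_hz = 250,
                            epoch_window_ms = c(-200, 1000), seed = 1L,
                            assign = list(early = "AD", late = "VD")) {
  stopifnot(inherits(early, "component_spec"),
            inherits(late, "component_spec"))
  if (length(early$topography) != length(late$topography)) {
    abort("early and late topographies must have the same length",
          class = "driftdecode_design_error")
  }
  step <- 1000 / sfreq_hz
  times_ms <- seq(epoch_window_ms[1], epoch_window_ms[2] - step / 2,
                  by = step)
  for (comp in list(early, late)) {
    if (comp$window_ms[1] < epoch_window_ms[1] ||
        comp$window_ms[2] > epoch_window_ms[2]) {
      abort("component window outside the epoch window",
            class = "driftdecode_design_error")
    }
  }
  n_trials <- nrow(schedule)
  n_channels <- length(early$topography)
  n_samples <- length(times_ms)

  set.seed(seed)
  noise <- array(rnorm(n_trials * n_channels * n_samples,
                       sd = early$noise_sd),
                 dim = c(n_trials, n_channels, n_samples))
  if (early$noise_model == "ar1") {
    phi <- early$ar1_coef
    # innovations scaled so the stationary sd stays noise_sd
    noise <- noise * sqrt(1 - phi^2)
    flat <- matrix(noise, nrow = n_trials * n_channels, ncol = n_samples)
    flat[, 1] <- flat[, 1] / sqrt(1 - phi^2)
    for (s in 2:n_samples) {
      flat[, s] <- phi * flat[, s - 1] + flat[, s]
    }
    noise <- array(flat, dim = dim(noise))
  }

  add_component <- function(data, comp, conditions) {
    idx <- which(schedule$condition %in% conditions)
    if (length(idx) == 0 || comp$amplitude == 0) return(data)
    bump <- comp$amplitude * outer(comp$topography,
                                   raised_cosine(times_ms, comp$window_ms))
    for (i in idx) data[i, , ] <- data[i, , ] + bump
    data
  }
  noise <- add_component(noise, early, assign$early)
  noise <- add_component(noise, late, assign$late)

  epoch_set(noise, times_ms = times_ms, labels = schedule$condition,
            sfreq_hz = sfreq_hz,
            meta = list(seed = seed, generator = "simulate_epochs"))
}

#' Synthetic continuous recording with event markers
#'
#' Noise-only multichannel recording with `n_events` evenly spaced event
#' markers, used to exercise the epoching stage. Events are placed
#' inside `[0.5 s, duration - 1.5 s]` so that full stimulus-locked
#' epochs fit around each.
#'
#' @param n_events Number of events (>= 0).
#' @param sfreq_hz Sampling rate.
#' @param duration_s Recording duration in seconds.
#' @param seed Integer seed.
#' @param n_channels Number of channels.
#' @param noise_sd Noise standard deviation.
#' @return A list with `eeg` (a [continuous_eeg]) and `events`
#'   (1-based sample indices).
#' @export
make_continuous_recording <- function(n_events, sfreq_hz = 250,
                                      duration_s = 10, seed = 1L,
                                      n_channels = 8, noise_sd = 1) {
  lo <- 0.5
  hi <- duration_s - 1.5
  if (n_events > 0 && hi < lo) {
    abort("duration too short for the requested events",
          class = "driftdecode_design_error")
  }
  set.seed(seed)
  n_samples <- round(duration_s * sfreq_hz)
  data <- matrix(rnorm(n_channels * n_samples, sd = noise_sd),
                 nrow = n_channels)
  events <- if (n_events == 0) {
    integer(0)
  } else if (n_events == 1) {
    round(mean(c(lo, hi)) * sfreq_hz) + 1L
  } else {
    round(seq(lo, hi, length.out = n_events) * sfreq_hz) + 1L
  }
  list(eeg = continuous_eeg(data, sfreq_hz = sfreq_hz), events = events)
}
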