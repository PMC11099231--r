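test_that("schedules honor the blocked design with ND first", {
  d <- design_spec() # 60 / 120 / 120
  sch <- make_trial_schedule(d, "visual", seed = 1)
  expect_equal(nrow(sch), 300)
  expect_true(all(sch$condition[1:60] == "ND"))
  expect_equal(as.vector(table(sch$condition)[c("ND", "AD", "VD")]),
               c(60, 120, 120))
  # congruency balanced within distractor blocks, none in ND
  expect_true(all(sch$congruency[sch$condition == "ND"] == "none"))
  for (cond in c("AD", "VD")) {
    tab <- table(sch$congruency[sch$condition == cond])
    expect_equal(tab[["congruent"]], tab[["incongruent"]])
  }
  # visual task: simultaneous presentation, onset 0
  expect_true(all(sch$target_onset_ms == 0))
  expect_identical(sch, make_trial_schedule(d, "visual", seed = 1))
})

test_that("auditory target onsets follow sequence position timing", {
  d <- design_spec(30, 30, 30)
  sch <- make_trial_schedule(d, "auditory", seed = 2)
  soa <- d$sound_dur_ms + d$gap_ms
  expect_true(all(sch$target_onset_ms %in% ((0:5) * soa)))
  expect_true(any(sch$target_onset_ms == 0)) # position 1 occurs
  expect_error(design_spec(n_nd = 0), class = "driftdecode_design_error")
})

test_that("sequence duration matches the sound/gap arithmetic", {
  expect_equal(sequence_duration(design_spec()), 1750)
  expect_equal(sequence_duration(design_spec(n_positions = 1)), 250)
  expect_equal(
    sequence_duration(design_spec(sound_dur_ms = 100, gap_ms = 10,
                                  n_positions = 3)), 320)
})

test_that("zero drift with central start gives symmetric choices", {
  d <- design_spec(3334, 3333, 3333)
  sch <- make_trial_schedule(d, "visual", seed = 3)
  beh <- simulate_behavior(sch, default_params3(v = c(0, 0, 0)), seed = 4)
  expect_equal(mean(beh$choice == "bird"), 0.5, tolerance = 0.03)
  expect_true(all(beh$rt_ms > 0.3 * 1000)) # rt exceeds non-decision time
})

test_that("simulated behavior matches an independent Euler-Maruyama oracle", {
  p <- ddm_params(v = 2, a = 1.5, z = 0.5, t = 0.3)
  n <- 10000
  d <- design_spec(n, 1, 1)
  sch <- make_trial_schedule(d, "visual", seed = 5)
  sch <- sch[sch$condition == "ND", ]
  beh <- simulate_behavior(sch, list(ND = p), seed = 6)
  oracle <- em_oracle(p$v, p$a, p$z, p$t, n, dt = 1e-4, seed = 7)
  expect_equal(mean(beh$rt_ms) / 1000, mean(oracle$rt), tolerance = 0.02)
  expect_equal(mean(beh$correct), mean(oracle$upper), tolerance = 0.02)
  expect_error(simulate_behavior(sch, list(AD = p), seed = 1),
               class = "driftdecode_design_error")
})

test_that("epoch generation is seed-deterministic and respects windows", {
  ep1 <- planted_epochs(n_per_class = 10, seed = 11)
  ep2 <- planted_epochs(n_per_class = 10, seed = 11)
  expect_identical(ep1$data, ep2$data)
  expect_error(
    planted_epochs(n_per_class = 10, window_early = c(-400, -300)),
    class = "driftdecode_design_error")
})

test_that("zero-amplitude components leave no class separation", {
  ep <- planted_epochs(n_per_class = 50, amp_early = 0, amp_late = 0,
                       seed = 12)
  X <- window_features(ep, 280, sliding_window_config())
  d_means <- colMeans(X[ep$labels == "AD", ]) -
    colMeans(X[ep$labels == "ND", ])
  expect_lt(max(abs(d_means)), 0.2) # pure noise at n = 50/class
})

test_that("class separation grows monotonically with planted amplitude", {
  amps <- c(0.5, 1.5, 3)
  sep <- sapply(seq_len(6), function(seed) {
    sapply(amps, function(amp) {
      ep <- planted_epochs(n_per_class = 40, amp_early = amp,
                           seed = 20 + seed)
      X <- window_features(ep, 280, sliding_window_config())
      ad <- X[ep$labels == "AD", ]
      nd <- X[ep$labels == "ND", ]
      S <- (cov(ad) + cov(nd)) / 2
      dm <- colMeans(ad) - colMeans(nd)
      sqrt(drop(t(dm) %*% solve(S, dm))) # Mahalanobis distance
    })
  })
  m <- rowMeans(sep)
  expect_true(all(diff(m) > 0))
})

test_that("ar1 noise reproduces the requested lag-1 autocorrelation", {
  sch <- tibble::tibble(
    subject_id = "S01", task = "visual", condition = rep("ND", 2),
    congruency = "none", target_onset_ms = 0, rt_ms = NA_real_,
    choice = NA_character_, correct = NA, target = "dog")
  spec <- component_spec(c(190, 370), rep(1, 4), amplitude = 0,
                         noise_sd = 1, noise_model = "ar1",
                         ar1_coef = 0.6)
  ep <- simulate_epochs(sch, spec, spec, sfreq_hz = 1000,
                        epoch_window_ms = c(0, 2000), seed = 30)
  ac <- apply(ep$data, c(1, 2), function(x) {
    cor(x[-1], x[-length(x)])
  })
  expect_equal(mean(ac), 0.6, tolerance = 0.05)
})

test_that("continuous recordings carry epochable event markers", {
  rec <- make_continuous_recording(2, sfreq_hz = 1000, duration_s = 10,
                                   seed = 40)
  expect_length(rec$events, 2)
  expect_equal(ncol(rec$eeg$data), 10000)
  ep <- epoch_continuous(rec$eeg, rec$events)
  expect_equal(dim(ep)[1], 2)

  rec0 <- make_continuous_recording(0, sfreq_hz = 250, duration_s = 5,
                                    seed = 41)
  expect_length(rec0$events, 0)
  expect_error(make_continuous_recording(3, duration_s = 1.2, seed = 1),
               class = "driftdecode_design_error")
})
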