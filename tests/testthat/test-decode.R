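test_that("the default window grid has 101 centers", {
  expect_length(window_centers(sliding_window_config()), 101)
})

test_that("window features average the samples inside the window", {
  # hand-built 2-trial, 2-channel, 4-sample tensor at 250 Hz
  data <- array(0, dim = c(2, 2, 4))
  data[1, 1, ] <- c(1, 2, 3, 4)
  data[1, 2, ] <- c(10, 20, 30, 40)
  data[2, 1, ] <- c(-1, -1, 1, 1)
  data[2, 2, ] <- c(0, 4, 0, 4)
  ep <- epoch_set(data, times_ms = c(0, 4, 8, 12), labels = c("ND", "AD"),
                  sfreq_hz = 250)
  cfg <- sliding_window_config(width_ms = 8, step_ms = 4,
                               center_start_ms = 4, center_end_ms = 8)
  X <- window_features(ep, 4, cfg) # window [0, 8): samples 1-2
  expect_equal(X, cbind(E001 = c(1.5, -1), E002 = c(15, 2)))
  # width of one sample period picks exactly that sample
  cfg1 <- sliding_window_config(width_ms = 4, step_ms = 4,
                                center_start_ms = 4, center_end_ms = 8)
  expect_equal(window_features(ep, 4, cfg1)[, 1], c(2, -1),
               ignore_attr = TRUE)
  # constant epochs give constant features
  epc <- epoch_set(array(3, dim = c(2, 2, 4)), c(0, 4, 8, 12),
                   c("ND", "AD"), 250)
  expect_true(all(window_features(epc, 4, cfg) == 3))
  expect_error(window_features(ep, 500, cfg),
               class = "driftdecode_range_error")
})

test_that("Az scoring counts ranked pairs with ties at one half", {
  expect_equal(az_score(c(0.1, 0.4, 0.35, 0.8), c("b", "b", "a", "a"),
                        positive = "a"), 0.75)
  expect_equal(az_score(rep(1, 10), rep(c("a", "b"), 5), positive = "a"),
               0.5)
  expect_equal(az_score(1:10, rep(c("b", "a"), each = 5),
                        positive = "a"), 1)
  expect_error(az_score(1:3, c("a", "a", "a")),
               class = "driftdecode_data_error")
})

test_that("Az equals brute-force pair counting on arbitrary scores", {
  set.seed(5)
  for (rep in 1:5) {
    y <- round(rnorm(100), 1) # coarse values force ties
    labels <- sample(rep(c("ND", "AD"), 50))
    pos <- y[labels == "ND"]
    neg <- y[labels == "AD"]
    brute <- mean(outer(pos, neg, function(a, b) {
      (a > b) + 0.5 * (a == b)
    }))
    expect_equal(az_score(y, labels), brute)
  }
})

test_that("the discriminator separates separable data and shrinks under l2", {
  X <- rbind(matrix(rnorm(40, 3), 20, 2), matrix(rnorm(40, -3), 20, 2))
  labels <- rep(c("ND", "AD"), each = 20)
  fit <- train_discriminator(X, labels, l2_lambda = 1e-3)
  scores <- X %*% fit$w + fit$b
  expect_true(all((scores > 0) == (labels == "ND")))
  # positive-mean orientation for the no-distractor class
  expect_gt(mean(scores[labels == "ND"]), 0)
  expect_lt(mean(scores[labels == "AD"]), 0)
  # heavy regularization on shuffled labels drives weights to zero
  set.seed(6)
  fit_big <- train_discriminator(X, sample(labels), l2_lambda = 1e6)
  expect_lt(sqrt(sum(fit_big$w^2)), 1e-3)
  expect_error(train_discriminator(X, rep("ND", 40)),
               class = "driftdecode_data_error")
})

test_that("the ridge fit matches an independent IRLS implementation", {
  set.seed(7)
  X <- matrix(rnorm(400), 200, 2)
  y01 <- rbinom(200, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 2]))
  labels <- ifelse(y01 == 1, "ND", "AD")
  fit <- train_discriminator(X, labels, l2_lambda = 1e-8)
  # oracle: base-R glm (independent IRLS path), effectively unpenalized
  oracle <- glm.fit(cbind(1, X), y01, family = binomial())$coefficients
  expect_equal(c(fit$b, fit$w), unname(oracle), tolerance = 1e-4)
})

test_that("null epochs decode at chance on average", {
  azs <- sapply(1:8, function(seed) {
    ep <- noise_epochs(n_trials = 100, n_channels = 16, seed = seed)
    mean(loo_discriminant(ep)$az)
  })
  # leave-one-out induces a small pessimistic bias, so the mean sits
  # just below 0.5 rather than above
  expect_lt(abs(mean(azs) - 0.5), 0.03)
})

test_that("a planted component is recovered at the right latency", {
  ep <- planted_epochs(n_per_class = 40, amp_early = 2, seed = 9)
  res <- loo_discriminant(ep)
  expect_gt(max(res$az), 0.9)
  peak <- res$window_centers_ms[which.max(res$az)]
  expect_gte(peak, 190 - 10)
  expect_lte(peak, 370 + 10)
  # peak_latency restricted to the early window agrees
  expect_equal(peak_latency(res, c(190, 370)),
               peak_latency(res, c(-100, 900)))
  # amplitude separation is negative under the sign convention
  expect_lt(component_amplitude_diff(res, peak_latency(res, c(190, 370))),
            0)
})

test_that("relabeling the classes flips y_out and preserves Az", {
  ep <- planted_epochs(n_per_class = 15, amp_early = 1, seed = 10)
  cfg <- sliding_window_config(center_start_ms = 200, center_end_ms = 300)
  res_nd <- loo_discriminant(ep, cfg = cfg, positive = "ND")
  res_ad <- loo_discriminant(ep, cfg = cfg, positive = "AD")
  expect_equal(res_ad$y_out, -res_nd$y_out, tolerance = 1e-6)
  expect_equal(res_ad$az, res_nd$az, tolerance = 1e-8)
})

test_that("forward models obey their algebraic identities", {
  set.seed(11)
  y <- rnorm(50)
  expect_equal(forward_model(matrix(y), y), 1)
  X <- cbind(y, rnorm(50))
  X[, 2] <- X[, 2] - y * sum(X[, 2] * y) / sum(y^2) # orthogonal channel
  a <- forward_model(X, y)
  expect_equal(a[1], 1)
  expect_equal(a[2], 0)
  expect_equal(forward_model(X, 3 * y), forward_model(X, y) / 3)
  expect_error(forward_model(X, rep(0, 50)),
               class = "driftdecode_degenerate_error")
})

test_that("peak latency handles monotone curves and ties", {
  res <- structure(list(window_centers_ms = seq(0, 50, 10),
                        az = c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)),
                   class = "discriminator_result")
  expect_equal(peak_latency(res, c(0, 50)), 50)
  res$az <- c(0.5, 0.9, 0.6, 0.9, 0.5, 0.4)
  expect_equal(peak_latency(res, c(0, 50)), 10) # earlier tie wins
  expect_error(peak_latency(res, c(200, 300)),
               class = "driftdecode_range_error")
})

test_that("permutation thresholds sit above chance and are reproducible", {
  ep <- noise_epochs(n_trials = 40, n_channels = 8, seed = 12)
  cfg <- sliding_window_config(center_start_ms = 0, center_end_ms = 200)
  thr1 <- permutation_threshold(ep, cfg = cfg, n_reps = 60, seed = 13,
                                mode = "cv")
  thr2 <- permutation_threshold(ep, cfg = cfg, n_reps = 60, seed = 13,
                                mode = "cv")
  expect_identical(thr1$threshold, thr2$threshold)
  expect_true(all(thr1$threshold > 0.5))
  expect_warning(
    permutation_threshold(ep, cfg = cfg, n_reps = 10, seed = 1,
                          mode = "cv"),
    "unstable")
})
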