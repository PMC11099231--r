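fake_fit <- function(draws_by_param, n_chains = 2) {
  pars <- names(draws_by_param)
  n <- nrow(draws_by_param[[1]])
  arr <- array(NA_real_, c(n, n_chains, length(pars)),
               dimnames = list(NULL, NULL, pars))
  for (i in seq_along(pars)) arr[, , i] <- draws_by_param[[i]]
  structure(list(group_draws = arr, n_chains = n_chains),
            class = "hddm_fit")
}

test_that("the model space numbers the eight variants canonically", {
  expect_equal(ddm_model_spec(1)$varying, character(0))
  expect_equal(ddm_model_spec(2)$varying, "v")
  expect_equal(ddm_model_spec(5)$varying, c("a", "t"))
  expect_equal(ddm_model_spec(8)$varying, c("a", "t", "v"))
  expect_equal(ddm_model_spec(varying = c("t", "v"))$model, 7L)
  expect_error(ddm_model_spec(9), class = "driftdecode_argument_error")
})

test_that("Gelman-Rubin separates converged from divergent chains", {
  set.seed(20)
  same <- fake_fit(list(theta = cbind(rnorm(5000), rnorm(5000))))
  rh <- gelman_rubin(same)
  expect_gte(rh[["theta"]], 0.99)
  expect_lte(rh[["theta"]], 1.05)

  apart <- fake_fit(list(theta = cbind(rnorm(1000, 0), rnorm(1000, 10))))
  expect_gt(gelman_rubin(apart)[["theta"]], 2)

  # identical chains: no between-chain variance beyond the split halves,
  # so split-R-hat sits at 1 up to within-chain sampling noise
  x <- rnorm(1000)
  ident <- fake_fit(list(theta = cbind(x, x)))
  expect_lt(abs(gelman_rubin(ident)[["theta"]] - 1), 0.05)

  one_chain <- fake_fit(list(theta = matrix(rnorm(100))), n_chains = 1)
  expect_error(gelman_rubin(one_chain),
               class = "driftdecode_diagnostic_error")
})

test_that("directional posterior probabilities behave at the extremes", {
  expect_equal(as.numeric(posterior_prob_greater(11:20, 1:10)), 1)
  set.seed(21)
  p_null <- posterior_prob_greater(rnorm(10000), rnorm(10000))
  expect_equal(as.numeric(p_null), 0.5, tolerance = 0.02)
  expect_false(attr(p_null, "significant"))
  p_sep <- posterior_prob_greater(rnorm(10000, 1, 0.1),
                                  rnorm(10000, 0, 0.1))
  expect_gt(as.numeric(p_sep), 0.99)
  expect_true(attr(p_sep, "significant"))
  # unequal lengths use the exact all-pairs fraction
  a <- c(1, 2, 3)
  b <- c(0, 2.5)
  expect_equal(as.numeric(posterior_prob_greater(a, b)), 4 / 6)
  expect_error(posterior_prob_greater(numeric(0), 1),
               class = "driftdecode_argument_error")
})

test_that("DIC reduces to the plug-in deviance for a degenerate posterior", {
  out <- dic_from_deviance(rep(123.4, 50), 123.4)
  expect_equal(as.numeric(out), 123.4)
  expect_equal(attr(out, "pD"), 0)
  # additivity of the deviance under dataset duplication
  out2 <- dic_from_deviance(2 * rep(123.4, 50), 2 * 123.4)
  expect_equal(attr(out2, "Dbar"), 2 * 123.4)
})

test_that("DIC matches a closed-form recomputation on a conjugate model", {
  # y ~ N(theta, 1) with a flat-ish prior: posterior draws in hand, the
  # deviance decomposition gives DIC = D(theta_bar) + 2 * n * var(theta)
  set.seed(22)
  y <- rnorm(30, 2)
  theta_draws <- rnorm(5000, mean(y), 1 / sqrt(30))
  dev <- vapply(theta_draws, function(th) sum((y - th)^2), numeric(1))
  theta_bar <- mean(theta_draws)
  ours <- dic_from_deviance(dev, sum((y - theta_bar)^2))
  closed <- sum((y - theta_bar)^2) +
    2 * 30 * mean((theta_draws - theta_bar)^2)
  expect_equal(as.numeric(ours), closed, tolerance = 1e-6)
})

test_that("the hierarchical sampler is seed-deterministic", {
  trials <- gen_group_trials(3, n_per_cond = 25)
  f1 <- fit_hddm(trials, ddm_model_spec(1), n_samples = 150,
                 n_burn = 50, n_chains = 1, seed = 23)
  f2 <- fit_hddm(trials, ddm_model_spec(1), n_samples = 150,
                 n_burn = 50, n_chains = 1, seed = 23)
  expect_identical(f1$group_draws, f2$group_draws)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("data requirements are enforced before sampling", {
  trials <- gen_subject_trials("S01", seed = 1, n_per_cond = 20)
  expect_error(fit_hddm(trials, ddm_model_spec(1), n_samples = 50,
                        n_burn = 10),
               class = "driftdecode_data_error")
  two <- gen_group_trials(2, n_per_cond = 10)
  missing_cond <- two[!(two$subject_id == "S02" & two$condition == "AD"), ]
  expect_error(fit_hddm(missing_cond, ddm_model_spec(2), n_samples = 50,
                        n_burn = 10),
               class = "driftdecode_data_error")
})

test_that("group means recover a planted drift effect with shrinkage", {
  params <- default_params3(v = c(0.8, 1.6, 2.2))
  trials <- gen_group_trials(6, n_per_cond = 80, params = params)
  fit <- fit_hddm(trials, ddm_model_spec(2), n_samples = 900,
                  n_burn = 300, n_chains = 2, seed = 24)
  est <- tidy(fit)
  v_nd <- est$estimate[est$term == "mu_v_ND"]
  v_ad <- est$estimate[est$term == "mu_v_AD"]
  v_vd <- est$estimate[est$term == "mu_v_VD"]
  expect_lt(v_nd, v_ad)
  expect_lt(v_ad, v_vd)
  expect_equal(v_nd, 0.8, tolerance = 0.3)
  expect_equal(v_vd, 2.2, tolerance = 0.4)
  # shrinkage: subject-level estimates sit closer to the group mean than
  # each subject's own maximum-likelihood drift
  theta_names <- dimnames(fit$subject_draws)[[3]]
  v_nd_cols <- grep("\\.v_ND$", theta_names)
  est_subj <- apply(fit$subject_draws[, , v_nd_cols, drop = FALSE], 3,
                    mean)
  ml_subj <- vapply(fit$subjects, function(sid) {
    sub <- trials[trials$subject_id == sid & trials$condition == "ND", ]
    optimize(function(v) {
      ddm_loglik(sub, ddm_params(v, 1.4, 0.5, 0.3))
    }, c(-1, 5), maximum = TRUE)$maximum
  }, numeric(1))
  expect_lt(mean(abs(est_subj - v_nd)), mean(abs(ml_subj - v_nd)) + 0.02)
})

test_that("zero generative drift leaves the drift posterior straddling 0", {
  trials <- gen_group_trials(6, n_per_cond = 80,
                             params = default_params3(v = c(0, 0, 0)))
  fit <- fit_hddm(trials, ddm_model_spec(1), n_samples = 700,
                  n_burn = 250, n_chains = 2, seed = 27)
  p <- as.numeric(posterior_prob_greater(group_draws(fit, "mu_v"),
                                         rep(0, 100)))
  expect_gt(p, 0.1)
  expect_lt(p, 0.9)
})

test_that("model comparison tables cover the variants and rank by DIC", {
  trials <- gen_group_trials(3, n_per_cond = 20)
  cmp <- compare_ddm_models(trials, models = 1:8, seed = 25,
                            n_samples = 120, n_burn = 40, n_chains = 1)
  expect_equal(nrow(cmp), 8)
  expect_equal(attr(cmp, "best_model"),
               cmp$model[which.min(cmp$dic)])
  expect_true(is.numeric(attr(cmp, "margin")))
})

test_that("DIC ordering is invariant to trial order", {
  trials <- gen_group_trials(3, n_per_cond = 20)
  shuffled <- trials[sample(nrow(trials)), ]
  f1 <- fit_hddm(trials, ddm_model_spec(1), n_samples = 200,
                 n_burn = 80, n_chains = 1, seed = 26)
  f2 <- fit_hddm(shuffled, ddm_model_spec(1), n_samples = 200,
                 n_burn = 80, n_chains = 1, seed = 26)
  expect_equal(as.numeric(dic(f1)), as.numeric(dic(f2)), tolerance = 2)
})
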