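#' Diffusion-model variant specification
#'
#' The model space crosses which of the three parameters of interest
#' (`v`, `a`, `t`) may differ between conditions, giving eight variants:
#' model 1 holds all three fixed; 2: `v` varies; 3: `a`; 4: `t`;
#' 5: `a, t`; 6: `v, a`; 7: `v, t`; 8: all three. The starting point
#' `z` is shared across conditions (one bias per subject) and estimated
#' freely unless `include_z = FALSE`, which pins it at 0.5.
#'
#' @param model Model number 1..8, or `NULL` to give `varying` directly.
#' @param varying Character subset of `c("v", "a", "t")`.
#' @param include_z Estimate the starting point (default) or fix at 0.5.
#' @return A `ddm_model_spec`.
#' @export
ddm_model_spec <- function(model = NULL, varying = NULL,
                           include_z = TRUE) {
  model_table <- list(character(0), "v", "a", "t", c("a", "t"),
                      c("v", "a"), c("v", "t"), c("v", "a", "t"))
  if (!is.null(model)) {
    if (!model %in% 1:8) {
      abort("model must be 1..8", class = "driftdecode_argument_error")
    }
    varying <- sort(model_table[[model]])
  } else {
    varying <- sort(intersect(c("v", "a", "t"), varying))
    model <- which(vapply(model_table,
                          function(m) setequal(m, varying), logical(1)))
  }
  structure(list(model = as.integer(model), varying = varying,
                 include_z = isTRUE(include_z)),
            class = "ddm_model_spec")
}

# group-mean prior settings per base parameter (natural scale for v,a,t;
# logit scale for z); weakly informative, truncations keep the
# likelihood defined
mu_prior <- function(base) {
  switch(base,
         v = list(mean = 2, sd = 3, lo = -Inf, hi = Inf),
         a = list(mean = 1.5, sd = 0.75, lo = 0.3, hi = Inf),
         t = list(mean = 0.4, sd = 0.2, lo = 0, hi = Inf),
         z = list(mean = 0, sd = 1, lo = -Inf, hi = Inf))
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- runif(1, plo, phi)
  u <- min(max(u, 1e-12), 1 - 1e-12)
  qnorm(u, mean, sd)
}

# subject parameter bookkeeping: instance table for a model spec and the
# condition levels present in the data
param_instances <- function(spec, conditions) {
  rows <- list()
  for (base in c("v", "a", "t")) {
    if (base %in% spec$varying) {
      for (cond in conditions) {
        rows[[length(rows) + 1]] <- list(
          name = paste0(base, "_", cond), base = base, cond = cond)
      }
    } else {
      rows[[length(rows) + 1]] <- list(name = base, base = base,
                                       cond = NA_character_)
    }
  }
  if (spec$include_z) {
    rows[[length(rows) + 1]] <- list(name = "z", base = "z",
                                     cond = NA_character_)
  }
  list(name = vapply(rows, `[[`, "", "name"),
       base = vapply(rows, `[[`, "", "base"),
       cond = vapply(rows, `[[`, "", "cond"))
}

# natural-scale parameter values for subject s in condition c
subject_cond_params <- function(theta_s, inst, cond, include_z) {
  pick <- function(base) {
    i <- which(inst$base == base & (is.na(inst$cond) | inst$cond == cond))
    theta_s[i]
  }
  z <- if (include_z) 1 / (1 + exp(-pick("z"))) else 0.5
  list(v = pick("v"), a = pick("a"), z = z, t = pick("t"))
}

#' Fit the hierarchical diffusion model
#'
#' Hierarchical Bayesian estimation across subjects and conditions by
#' adaptive Metropolis-within-Gibbs MCMC. Subject-level parameters are
#' drawn from group-level Gaussian distributions (one mean per
#' parameter-by-condition instance, one half-normal(1) SD per base
#' parameter); group means get conjugate Gibbs updates under weakly
#' informative Gaussian priors (`v`: N(2, 3^2); `a`: N(1.5, 0.75^2)
#' truncated above 0.3; `t`: N(0.4, 0.2^2) truncated at 0; logit `z`:
#' N(0, 1)), and subject parameters get componentwise random-walk
#' proposals whose step sizes adapt toward 44% acceptance during
#' burn-in (Robbins–Monro) and are then frozen. Invalid regions are
#' rejected through a zero Wiener first-passage-time likelihood. Two
#' chains are run by default so split-R-hat is available.
#'
#' @param trials A [trial_table] with complete behavior; at least 2
#'   subjects, and every subject must have trials in each condition a
#'   varying parameter needs.
#' @param spec A [ddm_model_spec].
#' @param n_samples Total MCMC draws per chain (default 5,500).
#' @param n_burn Burn-in draws discarded per chain (default 500).
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param seed Integer seed; chain `c` uses `seed + 1000 * (c - 1)`.
#' @param err_tol Density truncation tolerance.
#' @return An `hddm_fit` object: `group_draws` (kept x chain x
#'   parameter), `subject_draws`, `deviance` (kept x chain), plus the
#'   spec, instance table and data encoding.
#' @export
fit_hddm <- function(trials, spec = ddm_model_spec(8), n_samples = 5500,
                     n_burn = 500, n_chains = 2, seed = 1L,
                     err_tol = 1e-7) {
  trials <- validate_trial_table(trials, require_behavior = TRUE)
  stopifnot(inherits(spec, "ddm_model_spec"), n_samples > n_burn)
  subjects <- unique(trials$subject_id)
  if (length(subjects) < 2) {
    abort("hierarchical fitting needs at least 2 subjects",
          class = "driftdecode_data_error")
  }
  conditions <- sort(unique(trials$condition))
  if (length(spec$varying) > 0) {
    counts <- table(trials$subject_id, trials$condition)
    if (any(counts == 0)) {
      abort("every subject needs trials in every condition for this model",
            class = "driftdecode_data_error")
    }
  }
  inst <- param_instances(spec, conditions)
  n_inst <- length(inst$name)
  n_subj <- length(subjects)
  n_kept <- n_samples - n_burn

  # per subject-condition trial encoding (rt seconds, boundary, drift sign)
  enc <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    enc[[s]] <- lapply(conditions, function(cond) {
      sub <- trials[trials$subject_id == subjects[s] &
                      trials$condition == cond, , drop = FALSE]
      if (nrow(sub) == 0) return(NULL)
      encode_trials(sub)
    })
    names(enc[[s]]) <- conditions
  }

  ll_sc <- function(theta_s, s, cond) {
    e <- enc[[s]][[cond]]
    if (is.null(e)) return(0)
    p <- subject_cond_params(theta_s, inst, cond, spec$include_z)
    wfpt_loglik_cpp(e$rt_s, e$upper, e$drift_sign,
                    p$v, p$a, p$z, p$t, err_tol)
  }

  group_names <- c(paste0("mu_", inst$name),
                   paste0("sigma_", unique(inst$base)))
  bases <- unique(inst$base)
  group_draws <- array(NA_real_, c(n_kept, n_chains, length(group_names)),
                       dimnames = list(NULL, NULL, group_names))
  subj_names <- as.vector(outer(subjects, inst$name, paste, sep = "."))
  subject_draws <- array(NA_real_, c(n_kept, n_chains, n_subj * n_inst),
                         dimnames = list(NULL, NULL, subj_names))
  deviance <- matrix(NA_real_, n_kept, n_chains)

  init_step <- c(v = 0.3, a = 0.15, t = 0.04, z = 0.3)

  for (chain in seq_len(n_chains)) {
    set.seed(seed + 1000L * (chain - 1L))
    # initial values: mildly jittered, guaranteed-valid
    theta <- matrix(0, n_subj, n_inst)
    for (i in seq_len(n_inst)) {
      base <- inst$base[i]
      theta[, i] <- switch(base,
        v = 1 + rnorm(n_subj, 0, 0.2),
        a = 1.5 + abs(rnorm(n_subj, 0, 0.1)),
        t = vapply(seq_len(n_subj), function(s) {
          rts <- unlist(lapply(enc[[s]], function(e) {
            if (is.null(e)) NULL else e$rt_s
          }))
          0.5 * min(rts) * runif(1, 0.8, 1)
        }, numeric(1)),
        z = rnorm(n_subj, 0, 0.1))
    }
    mu <- vapply(seq_len(n_inst), function(i) mean(theta[, i]), numeric(1))
    sigma <- setNames(rep(0.3, length(bases)), bases)
    step_theta <- matrix(rep(init_step[inst$base], each = n_subj),
                         n_subj, n_inst)
    step_sigma <- setNames(rep(0.3, length(bases)), bases)
    step_nc_sigma <- setNames(rep(0.3, length(bases)), bases)
    step_nc_mu <- setNames(init_step[inst$base] / 2, inst$name)

    ll <- matrix(0, n_subj, length(conditions),
                 dimnames = list(NULL, conditions))
    for (s in seq_len(n_subj)) {
      for (cond in conditions) ll[s, cond] <- ll_sc(theta[s, ], s, cond)
    }
    if (any(!is.finite(ll))) {
      abort("invalid initialization: zero likelihood", # should not occur
            class = "driftdecode_fit_error")
    }

    for (iter in seq_len(n_samples)) {
      adapting <- iter <= n_burn
      gamma <- min(0.5, 1 / sqrt(max(iter, 10)))

      # 1. group means: conjugate Gibbs with truncated-normal priors
      for (i in seq_len(n_inst)) {
        pr <- mu_prior(inst$base[i])
        sg <- sigma[[inst$base[i]]]
        prec <- 1 / pr$sd^2 + n_subj / sg^2
        m_post <- (pr$mean / pr$sd^2 + sum(theta[, i]) / sg^2) / prec
        mu[i] <- rtruncnorm1(m_post, sqrt(1 / prec), pr$lo, pr$hi)
      }

      # 2. group sds: random-walk MH on log sigma, half-normal(1) prior
      for (base in bases) {
        ii <- which(inst$base == base)
        dev <- as.vector(theta[, ii, drop = FALSE]) -
          rep(mu[ii], each = n_subj)
        s_cur <- sigma[[base]]
        s_prop <- exp(log(s_cur) + rnorm(1, 0, step_sigma[[base]]))
        logpost <- function(sg) {
          sum(dnorm(dev, 0, sg, log = TRUE)) - sg^2 / 2 + log(sg)
        }
        acc <- log(runif(1)) < logpost(s_prop) - logpost(s_cur)
        if (acc) sigma[[base]] <- s_prop
        if (adapting) {
          step_sigma[[base]] <-
            exp(log(step_sigma[[base]]) + gamma * ((acc) - 0.44))
        }
      }

      # 2b. interweaved non-centered updates (ancillarity-sufficiency):
      # re-propose each group sd and mean while holding the standardized
      # subject effects fixed, so the sampler mixes even when the
      # between-subject sd collapses toward zero (the centered
      # parameterization's funnel)
      for (base in bases) {
        ii <- which(inst$base == base)
        conds_aff <- if (any(is.na(inst$cond[ii]))) {
          conditions
        } else {
          unique(inst$cond[ii])
        }
        s_cur <- sigma[[base]]
        eta <- sweep(theta[, ii, drop = FALSE], 2, mu[ii]) / s_cur
        s_prop <- exp(log(s_cur) + rnorm(1, 0, step_nc_sigma[[base]]))
        theta_prop <- theta
        theta_prop[, ii] <- sweep(eta * s_prop, 2, mu[ii], "+")
        ll_prop <- matrix(NA_real_, n_subj, length(conds_aff))
        for (s in seq_len(n_subj)) {
          ll_prop[s, ] <- vapply(conds_aff, function(cond) {
            ll_sc(theta_prop[s, ], s, cond)
          }, numeric(1))
        }
        delta <- sum(ll_prop) - sum(ll[, conds_aff]) +
          (-s_prop^2 / 2) - (-s_cur^2 / 2) +
          log(s_prop) - log(s_cur)
        acc <- is.finite(delta) && log(runif(1)) < delta
        if (acc) {
          sigma[[base]] <- s_prop
          theta <- theta_prop
          ll[, conds_aff] <- ll_prop
        }
        if (adapting) {
          step_nc_sigma[[base]] <-
            exp(log(step_nc_sigma[[base]]) + gamma * ((acc) - 0.44))
        }
        # non-centered translation of each group mean of this base
        for (i in ii) {
          conds_i <- if (is.na(inst$cond[i])) conditions else inst$cond[i]
          pr <- mu_prior(base)
          mu_prop <- mu[i] + rnorm(1, 0, step_nc_mu[i])
          if (mu_prop < pr$lo || mu_prop > pr$hi) next
          shift <- mu_prop - mu[i]
          theta_prop <- theta
          theta_prop[, i] <- theta[, i] + shift
          ll_prop <- matrix(NA_real_, n_subj, length(conds_i))
          for (s in seq_len(n_subj)) {
            ll_prop[s, ] <- vapply(conds_i, function(cond) {
              ll_sc(theta_prop[s, ], s, cond)
            }, numeric(1))
          }
          delta <- sum(ll_prop) - sum(ll[, conds_i]) +
            dnorm(mu_prop, pr$mean, pr$sd, log = TRUE) -
            dnorm(mu[i], pr$mean, pr$sd, log = TRUE)
          acc <- is.finite(delta) && log(runif(1)) < delta
          if (acc) {
            mu[i] <- mu_prop
            theta <- theta_prop
            ll[, conds_i] <- ll_prop
          }
          if (adapting) {
            step_nc_mu[i] <-
              exp(log(step_nc_mu[i]) + gamma * ((acc) - 0.44))
          }
        }
      }

      # 3. subject-level parameters: componentwise random-walk MH
      for (s in seq_len(n_subj)) {
        for (i in seq_len(n_inst)) {
          base <- inst$base[i]
          affected <- if (is.na(inst$cond[i])) conditions else inst$cond[i]
          prop <- theta[s, ]
          prop[i] <- theta[s, i] + rnorm(1, 0, step_theta[s, i])
          ll_new <- vapply(affected, function(cond) ll_sc(prop, s, cond),
                           numeric(1))
          delta <- sum(ll_new) - sum(ll[s, affected]) +
            dnorm(prop[i], mu[i], sigma[[base]], log = TRUE) -
            dnorm(theta[s, i], mu[i], sigma[[base]], log = TRUE)
          acc <- is.finite(delta) && log(runif(1)) < delta
          if (acc) {
            theta[s, i] <- prop[i]
            ll[s, affected] <- ll_new
          }
          if (adapting) {
            step_theta[s, i] <-
              exp(log(step_theta[s, i]) + gamma * ((acc) - 0.44))
          }
        }
      }

      if (iter > n_burn) {
        kk <- iter - n_burn
        group_draws[kk, chain, ] <- c(mu, unlist(sigma))
        subject_draws[kk, chain, ] <- as.vector(theta)
        deviance[kk, chain] <- -2 * sum(ll)
      }
    }
  }

  structure(list(group_draws = group_draws,
                 subject_draws = subject_draws, deviance = deviance,
                 spec = spec, instances = inst, subjects = subjects,
                 conditions = conditions, enc = enc,
                 n_samples = n_samples, n_burn = n_burn,
                 n_chains = n_chains, seed = seed, err_tol = err_tol),
            class = "hddm_fit")
}

#' @export
print.hddm_fit <- function(x, ...) {
  cat(sprintf(
    "<hddm_fit> model %d (varying: %s), %d subjects, %d chains x %d kept\n",
    x$spec$model,
    if (length(x$spec$varying)) paste(x$spec$varying, collapse = ",")
    else "none",
    length(x$subjects), x$n_chains, dim(x$group_draws)[1]))
  invisible(x)
}

# posterior mean of every subject-level parameter
posterior_mean_theta <- function(fit) {
  n_subj <- length(fit$subjects)
  n_inst <- length(fit$instances$name)
  matrix(apply(fit$subject_draws, 3, mean), n_subj, n_inst)
}

#' Deviance information criterion
#'
#' Conditional DIC on the subject-level parameters:
#' `DIC = Dbar + pD` with deviance `D(theta) = -2 log L(theta)`,
#' `Dbar` the posterior mean deviance (stored during sampling) and
#' `pD = Dbar - D(theta_bar)` the effective parameter count evaluated at
#' the posterior mean. Lower is better; a margin of 10 is conventionally
#' treated as decisive.
#'
#' @param fit An `hddm_fit`.
#' @return The DIC, with `Dbar` and `pD` as attributes.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "hddm_fit"))
  theta_bar <- posterior_mean_theta(fit)
  d_hat <- 0
  for (s in seq_along(fit$subjects)) {
    for (cond in fit$conditions) {
      e <- fit$enc[[s]][[cond]]
      if (is.null(e)) next
      p <- subject_cond_params(theta_bar[s, ], fit$instances, cond,
                               fit$spec$include_z)
      d_hat <- d_hat - 2 * wfpt_loglik_cpp(e$rt_s, e$upper, e$drift_sign,
                                           p$v, p$a, p$z, p$t, fit$err_tol)
    }
  }
  dic_from_deviance(as.vector(fit$deviance), d_hat)
}

#' DIC from a deviance trace
#'
#' The DIC formula on its own: `Dbar = mean(dev_draws)`,
#' `pD = Dbar - dev_at_mean`, `DIC = Dbar + pD`. Exposed separately so
#' the formula can be exercised on any model with a deviance trace.
#'
#' @param dev_draws Deviance evaluated at each posterior draw.
#' @param dev_at_mean Deviance at the posterior mean of the parameters.
#' @return DIC with attributes `Dbar` and `pD`.
#' @export
dic_from_deviance <- function(dev_draws, dev_at_mean) {
  dbar <- mean(dev_draws)
  pd <- dbar - dev_at_mean
  structure(dbar + pd, Dbar = dbar, pD = pd)
}

#' Gelman–Rubin convergence diagnostic
#'
#' Split-R-hat per group-level parameter: each chain is split in half
#' and the usual between/within variance ratio computed over the
#' resulting 2 x n_chains segments. Values at or below 1.1 indicate
#' acceptable convergence.
#'
#' @param fit An `hddm_fit` with at least 2 chains.
#' @return Named vector of R-hat values over group-level parameters.
#' @export
gelman_rubin <- function(fit) {
  stopifnot(inherits(fit, "hddm_fit"))
  if (fit$n_chains < 2) {
    abort("Gelman-Rubin requires at least 2 chains",
          class = "driftdecode_diagnostic_error")
  }
  pars <- dimnames(fit$group_draws)[[3]]
  vapply(pars, function(pn) {
    split_rhat(fit$group_draws[, , pn, drop = TRUE])
  }, numeric(1))
}

# split-Rhat of an [iterations x chains] draw matrix
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  segs <- do.call(cbind, lapply(seq_len(ncol(draws)), function(ch) {
    cbind(draws[seq_len(half), ch], draws[(n - half + 1):n, ch])
  }))
  n2 <- nrow(segs)
  means <- colMeans(segs)
  w <- mean(apply(segs, 2, var))
  b <- n2 * var(means)
  if (w == 0) return(1)
  sqrt(((n2 - 1) / n2 * w + b / n2) / w)
}

#' Compare diffusion-model variants by DIC
#'
#' Fits the requested model variants with identical sampler settings
#' and ranks them by DIC. The margin is the runner-up DIC minus the
#' best; a margin of at least 10 flags a decisive preference. A variant
#' whose fit fails is kept in the table with `NA` and noted.
#'
#' @inheritParams fit_hddm
#' @param models Integer vector of model numbers (default all 8).
#' @param ... Passed to [fit_hddm()] (`n_samples`, `n_burn`, ...).
#' @return A `ddm_model_comparison`: tibble of `model`, `varying`,
#'   `dic`, plus attributes `best_model`, `margin`, `significant`.
#' @export
compare_ddm_models <- function(trials, models = 1:8, seed = 1L, ...) {
  rows <- purrr::map(models, function(m) {
    spec <- ddm_model_spec(m)
    fit <- tryCatch(fit_hddm(trials, spec, seed = seed, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(model = m,
                     varying = paste(spec$varying, collapse = ","),
                     dic = NA_real_, note = conditionMessage(fit))
    } else {
      tibble::tibble(model = m,
                     varying = paste(spec$varying, collapse = ","),
                     dic = as.numeric(dic(fit)), note = "")
    }
  })
  tab <- dplyr::bind_rows(rows)
  ok <- which(!is.na(tab$dic))
  best <- ok[which.min(tab$dic[ok])]
  margin <- if (length(ok) > 1) {
    sort(tab$dic[ok])[2] - tab$dic[best]
  } else {
    NA_real_
  }
  structure(tab, best_model = tab$model[best], margin = margin,
            significant = isTRUE(margin >= 10),
            class = c("ddm_model_comparison", class(tab)))
}

#' Directional posterior probability
#'
#' Fraction of posterior draws with `a > b`: paired when the vectors
#' have equal length, otherwise the exact fraction over all cross
#' pairs. The conventional significance reading is `p < 0.05` or
#' `p > 0.95` (less than 5% overlap in the favored direction), attached
#' as attribute `significant`.
#'
#' @param draws_a,draws_b Posterior draw vectors.
#' @return Probability in `[0, 1]` with attribute `significant`.
#' @export
posterior_prob_greater <- function(draws_a, draws_b) {
  if (length(draws_a) == 0 || length(draws_b) == 0) {
    abort("draws must be non-empty", class = "driftdecode_argument_error")
  }
  p <- if (length(draws_a) == length(draws_b)) {
    mean(draws_a > draws_b)
  } else {
    sorted_a <- sort(draws_a)
    # findInterval counts a <= b, so this is the strict exceedance count
    counts <- length(sorted_a) - findInterval(draws_b, sorted_a)
    mean(counts / length(sorted_a))
  }
  structure(p, significant = p < 0.05 || p > 0.95)
}

#' Extract group-level posterior draws by name
#'
#' Convenience accessor pooling all chains: e.g.
#' `group_draws(fit, "mu_v_AD")`.
#'
#' @param fit An `hddm_fit`.
#' @param parameter Group-level parameter name.
#' @return Numeric vector of pooled draws.
#' @export
group_draws <- function(fit, parameter) {
  pars <- dimnames(fit$group_draws)[[3]]
  if (!parameter %in% pars) {
    abort(paste0("unknown parameter '", parameter, "'; available: ",
                 paste(pars, collapse = ", ")),
          class = "driftdecode_argument_error")
  }
  as.vector(fit$group_draws[, , parameter])
}
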