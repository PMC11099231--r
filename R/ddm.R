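#' Drift-diffusion model parameters
#'
#' The four-parameter diffusion model of two-choice decisions: noisy
#' evidence accumulates from a relative starting point `z` (in (0,1),
#' absolute start `z * a`) with drift rate `v` (evidence units per
#' second) between absorbing boundaries at 0 and `a`; the first passage
#' determines the choice, and the non-decision time `t` (seconds) is
#' added to the passage time. The diffusion coefficient is fixed at 1,
#' the standard identifiability convention. Inter-trial variability
#' parameters are not modeled.
#'
#' @param v Drift rate (evidence units / s). Positive drifts point to the
#'   upper boundary.
#' @param a Boundary separation (> 0).
#' @param z Relative starting point in (0, 1); 0.5 is unbiased.
#' @param t Non-decision time in seconds (>= 0).
#' @return A `ddm_params` list.
#' @export
ddm_params <- function(v = 1, a = 1.5, z = 0.5, t = 0.3) {
  if (!is.finite(v)) abort("v must be finite", class = "driftdecode_ddm_error")
  if (!is.finite(a) || a <= 0) {
    abort("a must be > 0", class = "driftdecode_ddm_error")
  }
  if (!is.finite(z) || z <= 0 || z >= 1) {
    abort("z must be in (0, 1)", class = "driftdecode_ddm_error")
  }
  if (!is.finite(t) || t < 0) {
    abort("t must be >= 0", class = "driftdecode_ddm_error")
  }
  structure(list(v = v, a = a, z = z, t = t), class = "ddm_params")
}

as_ddm_params <- function(p) {
  if (inherits(p, "ddm_params")) return(p)
  ddm_params(v = p$v, a = p$a, z = p$z, t = p$t)
}

#' Wiener first-passage-time density
#'
#' Density of the reaction time at a given boundary under the diffusion
#' model, computed by a dual series expansion with automatic small-time /
#' large-time selection, truncated at `err_tol`. Returns 0 (not an
#' error) for `rt <= t`, where a response is impossible.
#'
#' @param rt Reaction times in seconds (vectorized).
#' @param boundary `"upper"` or `"lower"`.
#' @param p A [ddm_params] object.
#' @param err_tol Series truncation tolerance.
#' @return Vector of densities (per second).
#' @export
wfpt_density <- function(rt, boundary = c("upper", "lower"), p,
                         err_tol = 1e-7) {
  boundary <- match.arg(boundary)
  p <- as_ddm_params(p)
  wfpt_density_cpp(as.numeric(rt), rep(boundary == "upper", length(rt)),
                   p$v, p$a, p$z, p$t, err_tol)
}

#' Simulate first passages of the diffusion
#'
#' Euler–Maruyama simulation with step `dt`; exact in the `dt -> 0`
#' limit. Used both as the behavioral data generator and as a
#' brute-force oracle for the series density.
#'
#' @inheritParams wfpt_density
#' @param n Number of trials.
#' @param seed Integer seed.
#' @param dt Time step in seconds.
#' @return A tibble with `rt` (seconds, including `t`) and `boundary`
#'   (`"upper"`/`"lower"`).
#' @export
simulate_ddm <- function(p, n, seed = 1L, dt = 1e-4) {
  p <- as_ddm_params(p)
  stopifnot(n >= 1)
  set.seed(seed)
  sim <- ddm_sim_cpp(as.integer(n), p$v, p$a, p$z, p$t, dt)
  tibble::tibble(
    rt = sim[, 1],
    boundary = ifelse(sim[, 2] > 0, "upper", "lower")
  )
}

#' Diffusion-model log-likelihood of a trial table
#'
#' Sums the log Wiener first-passage-time density over trials. Times are
#' converted from milliseconds (trial table convention) to seconds at
#' this boundary. Stimulus coding: the upper boundary is the "bird"
#' response; on trials whose target was "dog" the drift sign is flipped,
#' so a single positive `v` means evidence toward the correct category
#' and `z` is a response bias toward "bird". The target is recovered
#' from `choice` and `correct` (or a `target` column when present).
#' Returns `-Inf` as soon as any trial has zero density (e.g.
#' `rt <= t`).
#'
#' @param trials A [trial_table] with complete behavior.
#' @param p A [ddm_params] object.
#' @param err_tol Series truncation tolerance.
#' @return A single log-likelihood value.
#' @export
ddm_loglik <- function(trials, p, err_tol = 1e-7) {
  p <- as_ddm_params(p)
  enc <- encode_trials(trials)
  wfpt_loglik_cpp(enc$rt_s, enc$upper, enc$drift_sign,
                  p$v, p$a, p$z, p$t, err_tol)
}

# internal: trial table -> (rt seconds, chose-upper, drift sign) encoding
encode_trials <- function(trials) {
  if (any(is.na(trials$rt_ms)) || any(is.na(trials$choice))) {
    abort("trials must have complete rt_ms and choice",
          class = "driftdecode_schema_error")
  }
  target <- if ("target" %in% names(trials) && !any(is.na(trials$target))) {
    trials$target
  } else {
    if (any(is.na(trials$correct))) {
      abort("need either a target column or complete correct flags",
            class = "driftdecode_schema_error")
    }
    ifelse(trials$correct, trials$choice,
           ifelse(trials$choice == "bird", "dog", "bird"))
  }
  list(
    rt_s = trials$rt_ms / 1000,
    upper = as.integer(trials$choice == "bird"),
    drift_sign = ifelse(target == "bird", 1L, -1L)
  )
}
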