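#' Pipeline configuration
#'
#' A single nested list drives every CLI stage: the design block (trial
#' counts and sequence timing), generative DDM parameters per condition,
#' EEG synthesis settings (sampling rate, montage size, the two planted
#' component specs), decoding settings (sliding-window geometry,
#' regularization, permutation count) and group-level settings
#' (bootstrap reps, CI quantiles, k range). `default_config()` returns
#' the defaults; `read_config()` loads YAML (or JSON) and rejects
#' unknown keys so typos fail loudly.
#'
#' @return A named list with class `drift_config`.
#' @export
default_config <- function() {
  cfg <- list(
    seed = 1L,
    task = "visual",
    n_subjects = 2L,
    design = list(
      n_nd = 60L, n_ad = 120L, n_vd = 120L,
      sound_dur_ms = 250, gap_ms = 50, n_positions = 6L, nd_first = TRUE
    ),
    ddm = list(
      ND = list(v = 2.0, a = 1.4, z = 0.5, t = 0.3),
      AD = list(v = 1.5, a = 1.4, z = 0.5, t = 0.3),
      VD = list(v = 1.5, a = 1.4, z = 0.5, t = 0.3)
    ),
    eeg = list(
      sfreq_hz = 250, n_channels = 32L,
      epoch_window_ms = c(-200, 1000),
      early = list(window_ms = c(190, 370), amplitude = 1.0,
                   noise_sd = 1.0, noise_model = "white", ar1_coef = 0.5),
      late = list(window_ms = c(520, 630), amplitude = 1.0,
                  noise_sd = 1.0, noise_model = "white", ar1_coef = 0.5)
    ),
    decode = list(
      width_ms = 60, step_ms = 10, center_start_ms = -100,
      center_end_ms = 900, feature_mode = "window_mean",
      l2_lambda = 1e-3, n_permutations = 1000L, alpha = 0.05
    ),
    fit = list(
      model = 8L, n_samples = 5500L, n_burn = 500L, n_chains = 2L
    ),
    group = list(
      n_bootstrap = 1000L, ci = c(0.025, 0.975), k_range = c(2L, 6L)
    )
  )
  structure(cfg, class = c("drift_config", "list"))
}

check_unknown_keys <- function(user, template, path = "") {
  if (!is.list(user) || !is.list(template)) return(invisible())
  extra <- setdiff(names(user), names(template))
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ",
                 paste0(path, extra, collapse = ", ")),
          class = "driftdecode_config_error")
  }
  for (k in names(user)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      check_unknown_keys(user[[k]], template[[k]], paste0(path, k, "."))
    }
  }
  invisible()
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  stopifnot_config <- function(ok, msg) {
    if (!isTRUE(ok)) abort(msg, class = "driftdecode_config_error")
  }
  d <- cfg$design
  stopifnot_config(all(c(d$n_nd, d$n_ad, d$n_vd) >= 1),
                   "design trial counts must be >= 1")
  stopifnot_config(d$sound_dur_ms > 0 && d$gap_ms >= 0 && d$n_positions >= 1,
                   "design timing must be positive")
  dec <- cfg$decode
  stopifnot_config(dec$width_ms > 0 && dec$step_ms > 0,
                   "decode window width and step must be > 0")
  stopifnot_config(dec$center_start_ms < dec$center_end_ms,
                   "decode window range must be increasing")
  stopifnot_config(dec$alpha > 0 && dec$alpha < 1,
                   "decode alpha must be in (0, 1)")
  stopifnot_config(dec$l2_lambda >= 0, "l2_lambda must be >= 0")
  stopifnot_config(cfg$eeg$sfreq_hz > 0 && cfg$eeg$n_channels >= 1,
                   "eeg block must have positive sfreq and channels")
  stopifnot_config(cfg$fit$n_samples > cfg$fit$n_burn,
                   "fit n_samples must exceed n_burn")
  stopifnot_config(cfg$group$n_bootstrap >= 1, "n_bootstrap must be >= 1")
  structure(cfg, class = c("drift_config", "list"))
}

#' @rdname default_config
#' @param path Path to a YAML or JSON configuration file; only keys that
#'   differ from the defaults need to be present.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "driftdecode_io_error")
  }
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  base <- default_config()
  check_unknown_keys(user, base)
  validate_config(merge_config(base, user))
}
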