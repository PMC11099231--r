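#' Behavioral trial filters
#'
#' Three row-removal filters feed the descriptive summaries and the
#' hierarchical diffusion-model fits. Filters never alter values; each
#' attaches a removal report (per-subject counts) retrievable with
#' [filter_report()]. The analysis chain mirrors the emulated study:
#' premature-response removal, then the 3-SD rule for descriptives, or
#' the 5%-per-tail trim for model fitting.
#'
#' @name behavior_filters
NULL

attach_report <- function(trials, report) {
  attr(trials, "filter_report") <- report
  trials
}

#' Retrieve the removal report of the last filter applied
#'
#' @param trials A filtered [trial_table].
#' @return A tibble of per-subject removal counts, or `NULL`.
#' @export
filter_report <- function(trials) attr(trials, "filter_report")

#' @describeIn behavior_filters Remove premature responses: trials with
#'   `rt_ms <= 0`, i.e. responses at or before target onset (RT is
#'   measured from target onset, so these carry no decision information).
#' @param trials A [trial_table] with `rt_ms`.
#' @return The filtered table (rows preserved in order).
#' @export
filter_premature <- function(trials) {
  trials <- validate_trial_table(trials)
  premature <- !is.na(trials$rt_ms) & trials$rt_ms <= 0
  report <- trials |>
    dplyr::mutate(premature_flag = premature) |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(n_removed = sum(.data$premature_flag),
                     n_total = dplyr::n(), .groups = "drop")
  attach_report(trials[!premature, , drop = FALSE], report)
}

#' @describeIn behavior_filters Per-subject 3-SD rule: remove trials
#'   whose RT deviates from that subject's mean RT by more than
#'   `k` sample standard deviations (n-1 denominator), pooled across
#'   conditions. Subjects with fewer than 2 trials pass through with a
#'   warning; a zero SD removes nothing.
#' @param k Number of standard deviations.
#' @export
trim_rt_sd <- function(trials, k = 3) {
  trials <- validate_trial_table(trials)
  keep <- rep(TRUE, nrow(trials))
  for (sid in unique(trials$subject_id)) {
    idx <- which(trials$subject_id == sid)
    if (length(idx) < 2) {
      warn(paste0("subject ", sid, " has < 2 trials; passed unfiltered"))
      next
    }
    rt <- trials$rt_ms[idx]
    m <- mean(rt)
    s <- sd(rt)
    if (is.na(s) || s == 0) next
    keep[idx] <- abs(rt - m) <= k * s
  }
  report <- trials |>
    dplyr::mutate(keep_flag = keep) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_removed = sum(!.data$keep_flag),
                     n_total = dplyr::n(),
                     pct_removed = 100 * mean(!.data$keep_flag),
                     .groups = "drop")
  attach_report(trials[keep, , drop = FALSE], report)
}

#' @describeIn behavior_filters Per-subject 5%-tail trim used before
#'   diffusion-model fitting: remove trials strictly below the
#'   `tail` quantile or strictly above the `1 - tail` quantile of that
#'   subject's RT distribution (linear-interpolation quantiles,
#'   `type = 7`). `tail = 0` is the identity; identical RTs are never
#'   removed.
#' @param tail Fraction per tail, `0 <= tail < 0.5`.
#' @export
trim_rt_tails <- function(trials, tail = 0.05) {
  if (tail < 0 || tail >= 0.5) {
    abort("tail must be in [0, 0.5)", class = "driftdecode_argument_error")
  }
  trials <- validate_trial_table(trials)
  if (tail == 0) return(attach_report(trials, NULL))
  keep <- rep(TRUE, nrow(trials))
  for (sid in unique(trials$subject_id)) {
    idx <- which(trials$subject_id == sid)
    rt <- trials$rt_ms[idx]
    q <- quantile(rt, c(tail, 1 - tail), type = 7, names = FALSE)
    keep[idx] <- rt >= q[1] & rt <= q[2]
  }
  report <- trials |>
    dplyr::mutate(keep_flag = keep) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_removed = sum(!.data$keep_flag),
                     n_total = dplyr::n(), .groups = "drop")
  attach_report(trials[keep, , drop = FALSE], report)
}

#' Per-condition behavioral summaries
#'
#' Subject-first aggregation: each subject's mean accuracy and RT per
#' task x condition cell is computed first, then the mean and SD across
#' subjects — the form in which group results are conventionally
#' reported. Empty cells are simply absent from the output.
#'
#' @param trials A [trial_table] with complete behavior.
#' @return A tibble with one row per task x condition: `n_subjects`,
#'   `mean_acc`, `sd_acc`, `mean_rt_ms`, `sd_rt_ms`.
#' @export
condition_summaries <- function(trials) {
  trials <- validate_trial_table(trials, require_behavior = TRUE)
  if (nrow(trials) == 0) {
    abort("cannot summarise an empty trial table",
          class = "driftdecode_argument_error")
  }
  trials |>
    dplyr::group_by(.data$task, .data$condition, .data$subject_id) |>
    dplyr::summarise(acc = mean(.data$correct), rt = mean(.data$rt_ms),
                     .groups = "drop") |>
    dplyr::group_by(.data$task, .data$condition) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      mean_acc = mean(.data$acc), sd_acc = sd(.data$acc),
      mean_rt_ms = mean(.data$rt), sd_rt_ms = sd(.data$rt),
      .groups = "drop"
    )
}
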