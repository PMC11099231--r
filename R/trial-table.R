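#' Behavioral trial tables
#'
#' A trial table is a tibble with one row per behavioral trial and the
#' columns `subject_id`, `task` (`"visual"`/`"auditory"`), `condition`
#' (`"ND"`, `"AD"`, `"VD"`: no-distractor, auditory-distractor,
#' visual-distractor), `congruency` (`"congruent"`, `"incongruent"`,
#' `"none"`), `target_onset_ms`, `rt_ms` (reaction time measured from
#' target onset), `choice` (`"dog"`/`"bird"`) and `correct` (logical).
#' Generated schedules additionally carry a `target` column with the
#' trial's true category. `rt_ms`, `choice` and `correct` may be `NA`
#' in a schedule that has not yet been simulated or run.
#'
#' @name trial_table
NULL

trial_table_columns <- c(
  "subject_id", "task", "condition", "congruency",
  "target_onset_ms", "rt_ms", "choice", "correct"
)

#' Validate a trial table
#'
#' Checks the schema and invariants of a [trial_table]: required columns,
#' legal factor levels, `congruency == "none"` on ND trials, finite
#' non-missing onsets, non-empty subject ids.
#'
#' @param trials A data frame of trials.
#' @param require_behavior If `TRUE`, `rt_ms`/`choice`/`correct` must be
#'   complete (needed for fitting); schedules may leave them `NA`.
#' @return The validated table as a tibble, invisibly unchanged.
#' @export
validate_trial_table <- function(trials, require_behavior = FALSE) {
  missing_cols <- setdiff(trial_table_columns, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "driftdecode_schema_error")
  }
  trials <- tibble::as_tibble(trials)
  if (nrow(trials) == 0) return(trials)
  if (any(is.na(trials$subject_id) | trials$subject_id == "")) {
    abort("subject_id must be non-empty", class = "driftdecode_schema_error")
  }
  if (!all(trials$task %in% c("visual", "auditory"))) {
    abort("task must be 'visual' or 'auditory'",
          class = "driftdecode_schema_error")
  }
  if (!all(trials$condition %in% c("ND", "AD", "VD"))) {
    abort("condition must be one of ND, AD, VD",
          class = "driftdecode_schema_error")
  }
  if (!all(trials$congruency %in% c("congruent", "incongruent", "none"))) {
    abort("congruency must be congruent, incongruent or none",
          class = "driftdecode_schema_error")
  }
  nd <- trials$condition == "ND"
  if (any(trials$congruency[nd] != "none")) {
    abort("ND trials must have congruency 'none'",
          class = "driftdecode_schema_error")
  }
  if (any(!is.finite(trials$target_onset_ms) | trials$target_onset_ms < 0)) {
    abort("target_onset_ms must be finite and non-negative",
          class = "driftdecode_schema_error")
  }
  rt_known <- !is.na(trials$rt_ms)
  if (any(rt_known & !is.finite(trials$rt_ms))) {
    abort("rt_ms must be finite where present",
          class = "driftdecode_schema_error")
  }
  if (require_behavior &&
      (any(!rt_known) || any(is.na(trials$choice)) ||
       any(is.na(trials$correct)))) {
    abort("rt_ms, choice and correct must be complete for this operation",
          class = "driftdecode_schema_error")
  }
  if (any(!is.na(trials$choice) & !trials$choice %in% c("dog", "bird"))) {
    abort("choice must be 'dog' or 'bird'",
          class = "driftdecode_schema_error")
  }
  trials
}

trial_table_col_types <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    task = readr::col_character(),
    condition = readr::col_character(),
    congruency = readr::col_character(),
    target_onset_ms = readr::col_double(),
    rt_ms = readr::col_double(),
    choice = readr::col_character(),
    correct = readr::col_logical(),
    .default = readr::col_guess()
  )
}

#' Read and write trial tables
#'
#' Trial tables are stored as UTF-8 CSV with a header row. Reading
#' validates the schema; row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return `read_trial_table()` returns a validated [trial_table] tibble.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "driftdecode_io_error")
  }
  # readr reports parse problems both as a warning and in problems();
  # the warning is muffled and the structured record inspected instead
  trials <- withCallingHandlers(
    readr::read_csv(path, col_types = trial_table_col_types(),
                    progress = FALSE),
    warning = function(w) invokeRestart("muffleWarning")
  )
  probs <- readr::problems(trials)
  if (nrow(probs) > 0) {
    abort(paste0("unparsable value(s) in ", path, " at row(s) ",
                 paste(unique(probs$row), collapse = ", ")),
          class = "driftdecode_parse_error")
  }
  validate_trial_table(trials)
}

#' @rdname read_trial_table
#' @param trials A [trial_table] tibble.
#' @export
write_trial_table <- function(trials, path) {
  trials <- validate_trial_table(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}
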