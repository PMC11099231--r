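#' Sliding-window discriminator configuration
#'
#' Geometry and regularization of the single-trial sliding-window
#' analysis: 60 ms windows stepped every 10 ms, window centers from
#' -100 to 900 ms relative to stimulus onset (101 windows at the
#' defaults). `feature_mode = "window_mean"` averages the samples inside
#' a window per channel (one feature per channel); `"all_samples"`
#' instead concatenates every sample as its own feature.
#'
#' @param width_ms Window width (> 0).
#' @param step_ms Center spacing (> 0).
#' @param center_start_ms,center_end_ms Window-center range.
#' @param feature_mode `"window_mean"` or `"all_samples"`.
#' @param l2_lambda Ridge penalty of the logistic discriminator (>= 0);
#'   a small penalty keeps the 98-channel fit stable with few trials.
#' @return A `sliding_window_config` list.
#' @export
sliding_window_config <- function(width_ms = 60, step_ms = 10,
                                  center_start_ms = -100,
                                  center_end_ms = 900,
                                  feature_mode = c("window_mean",
                                                   "all_samples"),
                                  l2_lambda = 1e-3) {
  feature_mode <- match.arg(feature_mode)
  if (width_ms <= 0 || step_ms <= 0 || center_start_ms >= center_end_ms ||
      l2_lambda < 0) {
    abort("invalid sliding-window configuration",
          class = "driftdecode_argument_error")
  }
  structure(list(width_ms = width_ms, step_ms = step_ms,
                 center_start_ms = center_start_ms,
                 center_end_ms = center_end_ms,
                 feature_mode = feature_mode, l2_lambda = l2_lambda),
            class = "sliding_window_config")
}

#' @rdname sliding_window_config
#' @param cfg A `sliding_window_config`.
#' @return `window_centers()`: the vector of window centers in ms.
#' @export
window_centers <- function(cfg) {
  seq(cfg$center_start_ms, cfg$center_end_ms, by = cfg$step_ms)
}

# positive class = no-distractor by convention; returns 0/1 vector
binary_labels <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    abort("exactly two classes are required",
          class = "driftdecode_data_error")
  }
  if (is.null(positive)) positive <- if ("ND" %in% lev) "ND" else lev[1]
  if (!positive %in% lev) {
    abort(paste0("positive class '", positive, "' not present"),
          class = "driftdecode_data_error")
  }
  list(y01 = as.numeric(labels == positive), positive = positive,
       negative = setdiff(lev, positive))
}

#' Per-window feature matrix
#'
#' Extracts the discriminator features of one sliding window: with
#' `feature_mode = "window_mean"`, the per-trial, per-channel mean over
#' samples in the half-open window `[center - width/2, center + width/2)`.
#'
#' @param epochs An [epoch_set].
#' @param center_ms Window center in ms.
#' @param cfg A [sliding_window_config].
#' @return A numeric matrix `[n_trials x n_features]`.
#' @export
window_features <- function(epochs, center_ms, cfg = sliding_window_config()) {
  half <- cfg$width_ms / 2
  inside <- epochs$times_ms >= center_ms - half &
    epochs$times_ms < center_ms + half
  if (!any(inside)) {
    abort(sprintf("window centered at %g ms contains no samples",
                  center_ms),
          class = "driftdecode_range_error")
  }
  sl <- epochs$data[, , inside, drop = FALSE]
  if (cfg$feature_mode == "window_mean") {
    X <- apply(sl, c(1, 2), mean)
    colnames(X) <- epochs$channel_names
    X
  } else {
    d <- dim(sl)
    matrix(sl, nrow = d[1], ncol = d[2] * d[3])
  }
}

#' Train the spatial discriminator of one window
#'
#' L2-regularized logistic regression learning the channel weighting
#' `w` such that the discriminant output `y = w'x + b` has positive mean
#' for the no-distractor class and negative mean for the distractor
#' class.
#'
#' @param X Feature matrix `[n_trials x D]`.
#' @param labels Two-class label vector.
#' @param l2_lambda Ridge penalty.
#' @param positive Label treated as the positive (no-distractor) class;
#'   defaults to `"ND"` when present.
#' @return A list with `w` (length D), `b`, and `positive`.
#' @export
train_discriminator <- function(X, labels, l2_lambda = 1e-3,
                                positive = NULL) {
  if (anyNA(X)) abort("features contain NA", class = "driftdecode_data_error")
  bl <- binary_labels(labels, positive)
  fit <- ridge_logistic_cpp(as.matrix(X), bl$y01, l2_lambda)
  list(w = as.numeric(fit$w), b = as.numeric(fit$b),
       positive = bl$positive)
}

#' Area under the ROC curve of a discriminant output
#'
#' Az of `y` as a score for the positive class, computed from average
#' ranks so tied scores count 1/2. Chance is 0.5.
#'
#' @param y Numeric score per trial.
#' @param labels Two-class label vector.
#' @param positive Positive class (default `"ND"` when present).
#' @return Az in `[0, 1]`.
#' @export
az_score <- function(y, labels, positive = NULL) {
  bl <- binary_labels(labels, positive)
  pos <- bl$y01 == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  r <- rank(y, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Leave-one-trial-out sliding-window discrimination
#'
#' For every window center: each trial is scored by a discriminator
#' trained on all other trials (leave-one-trial-out), giving
#' out-of-sample component amplitudes `y_out[window, trial]`; the Az per
#' window is the ROC area of those held-out scores. Window weights come
#' from a final fit on all trials, and the corresponding forward model
#' `a = X'y / (y'y)` gives the scalp projection of each window's
#' component.
#'
#' @param epochs An [epoch_set].
#' @param labels Trial labels (default: the epoch labels). Exactly two
#'   classes with at least `min_per_class` trials each.
#' @param cfg A [sliding_window_config].
#' @param positive Positive (no-distractor) class.
#' @param min_per_class Minimum trials per class.
#' @return A `discriminator_result` with elements `window_centers_ms`,
#'   `az`, `y_out`, `weights`, `forward_models`, `labels`, `positive`,
#'   `cfg`.
#' @export
loo_discriminant <- function(epochs, labels = NULL,
                             cfg = sliding_window_config(),
                             positive = NULL, min_per_class = 10) {
  if (is.null(labels)) labels <- epochs$labels
  bl <- binary_labels(labels, positive)
  if (min(table(bl$y01)) < min_per_class) {
    abort(paste0("each class needs at least ", min_per_class, " trials"),
          class = "driftdecode_data_error")
  }
  centers <- window_centers(cfg)
  n_trials <- dim(epochs$data)[1]
  n_channels <- dim(epochs$data)[2]
  y_out <- matrix(NA_real_, length(centers), n_trials)
  az <- numeric(length(centers))
  weights <- matrix(NA_real_, length(centers), n_channels)
  fmodels <- matrix(NA_real_, length(centers), n_channels)
  for (j in seq_along(centers)) {
    X <- window_features(epochs, centers[j], cfg)
    y_out[j, ] <- as.numeric(loo_scores_cpp(X, bl$y01, cfg$l2_lambda))
    az[j] <- az_score(y_out[j, ], labels, bl$positive)
    full <- ridge_logistic_cpp(X, bl$y01, cfg$l2_lambda)
    if (cfg$feature_mode == "window_mean") {
      w <- as.numeric(full$w)
      weights[j, ] <- w
      y_in <- as.numeric(X %*% w + full$b)
      fmodels[j, ] <- forward_model(X, y_in)
    }
  }
  structure(list(window_centers_ms = centers, az = az, y_out = y_out,
                 weights = weights, forward_models = fmodels,
                 labels = as.character(labels), positive = bl$positive,
                 negative = bl$negative, cfg = cfg),
            class = "discriminator_result")
}

#' @export
print.discriminator_result <- function(x, ...) {
  cat(sprintf(
    "<discriminator_result> %d windows (%g..%g ms), %d trials (%s vs %s)\n",
    length(x$window_centers_ms), min(x$window_centers_ms),
    max(x$window_centers_ms), ncol(x$y_out), x$positive, x$negative))
  cat(sprintf("peak Az %.3f at %g ms\n", max(x$az),
              x$window_centers_ms[which.max(x$az)]))
  invisible(x)
}

#' Permutation significance threshold for Az
#'
#' Estimates the null distribution of Az per window by repeatedly
#' permuting the trial labels (without replacement) and re-running the
#' cross-validated discrimination; the threshold at each window is the
#' `1 - alpha` quantile of its null Az values, used instead of assuming
#' 0.5 as chance. `mode = "loo"` replicates the full leave-one-out
#' procedure per permutation; `mode = "cv"` uses stratified k-fold
#' cross-validation, a fast surrogate for permutation counts at desk
#' scale.
#'
#' @inheritParams loo_discriminant
#' @param n_reps Number of permutations.
#' @param alpha Significance level in (0, 1).
#' @param seed Integer seed.
#' @param mode `"loo"` or `"cv"`.
#' @param folds Folds for `"cv"` mode.
#' @return A tibble with `window_center_ms`, `threshold` and, as
#'   attribute `"null_az"`, the `n_reps x n_windows` null matrix.
#' @export
permutation_threshold <- function(epochs, labels = NULL,
                                  cfg = sliding_window_config(),
                                  n_reps = 1000, alpha = 0.05, seed = 1L,
                                  positive = NULL,
                                  mode = c("loo", "cv"), folds = 10) {
  mode <- match.arg(mode)
  if (is.null(labels)) labels <- epochs$labels
  bl <- binary_labels(labels, positive)
  if (n_reps < 20) {
    warn("fewer than 20 permutations: threshold quantile is unstable")
  }
  centers <- window_centers(cfg)
  features <- lapply(centers, function(cc) window_features(epochs, cc, cfg))
  set.seed(seed)
  n <- length(bl$y01)
  null_az <- matrix(NA_real_, n_reps, length(centers))
  for (r in seq_len(n_reps)) {
    perm <- sample.int(n)
    yp <- bl$y01[perm]
    fold_id <- NULL
    if (mode == "cv") {
      # stratified folds over the permuted labels
      fold_id <- integer(n)
      for (cls in c(0, 1)) {
        idx <- which(yp == cls)
        fold_id[idx] <- rep_len(seq_len(folds), length(idx))[
          sample.int(length(idx))]
      }
    }
    for (j in seq_along(centers)) {
      scores <- if (mode == "loo") {
        loo_scores_cpp(features[[j]], yp, cfg$l2_lambda)
      } else {
        cv_scores_cpp(features[[j]], yp, cfg$l2_lambda, fold_id)
      }
      null_az[r, j] <- az_from_scores(as.numeric(scores), yp)
    }
  }
  thr <- apply(null_az, 2, quantile, probs = 1 - alpha, names = FALSE)
  out <- tibble::tibble(window_center_ms = centers, threshold = thr)
  attr(out, "null_az") <- null_az
  attr(out, "alpha") <- alpha
  out
}

# AUC from scores against a 0/1 vector (positive = 1)
az_from_scores <- function(y, y01) {
  pos <- y01 == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  r <- rank(y, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Forward model of a discriminant component
#'
#' Channel-space projection `a = X'y / (y'y)`: the normalized
#' correlation between the discriminant output and the activity at each
#' sensor, interpretable as the component's scalp topography.
#'
#' @param X Feature matrix `[n_trials x D]`.
#' @param y Discriminant output per trial (not all zero).
#' @return Numeric vector of length `D`.
#' @export
forward_model <- function(X, y) {
  ss <- sum(y^2)
  if (ss <= 0) {
    abort("discriminant output is identically zero",
          class = "driftdecode_degenerate_error")
  }
  as.numeric(crossprod(as.matrix(X), y) / ss)
}

#' Peak discrimination latency inside a component window
#'
#' The window center with maximal Az inside `[start, end]` (inclusive);
#' ties break toward the earlier center.
#'
#' @param result A `discriminator_result`.
#' @param window_ms Length-2 search window in ms.
#' @return Latency in ms.
#' @export
peak_latency <- function(result, window_ms) {
  inside <- which(result$window_centers_ms >= window_ms[1] &
                    result$window_centers_ms <= window_ms[2])
  if (length(inside) == 0) {
    abort("no window centers inside the requested range",
          class = "driftdecode_range_error")
  }
  best <- inside[which.max(result$az[inside])] # which.max takes first tie
  result$window_centers_ms[best]
}

#' Component amplitude separation at a latency
#'
#' Mean out-of-sample discriminant amplitude over distractor trials
#' minus the mean over no-distractor trials at the given window. Under
#' the sign convention (no-distractor positive) a planted distractor
#' component yields a negative separation.
#'
#' @param result A `discriminator_result`.
#' @param latency_ms A window center on the result's grid.
#' @return The amplitude difference (distractor minus no-distractor).
#' @export
component_amplitude_diff <- function(result, latency_ms) {
  j <- match(latency_ms, result$window_centers_ms)
  if (is.na(j)) {
    abort("latency_ms is not on the window grid",
          class = "driftdecode_range_error")
  }
  y <- result$y_out[j, ]
  mean(y[result$labels != result$positive]) -
    mean(y[result$labels == result$positive])
}
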