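#' Temporal clustering of forward-model topographies
#'
#' Partitions the sliding-window forward models into temporally distinct
#' scalp representations: k-means (Euclidean metric, 10 seeded restarts)
#' on the topography vectors for each k in `k_range`, with k selected by
#' the maximal mean silhouette value. Component windows are the maximal
#' contiguous runs of a common cluster label along the window grid;
#' transition points sit midway between adjacent runs.
#'
#' @param forward_models Matrix `[n_windows x n_channels]` of forward
#'   models, rows ordered along the time grid.
#' @param window_centers_ms Optional window centers (for ms-valued
#'   windows and transitions in the report).
#' @param k_range Candidate cluster counts (default 2..6).
#' @param seed Integer seed for the k-means restarts.
#' @param n_restarts Random restarts per k.
#' @param normalize Scale each forward model to unit norm before
#'   clustering (default). A component's forward-model magnitude waxes
#'   and wanes with its time course while its direction — the scalp
#'   pattern proper — stays put; normalizing makes the clustering answer
#'   "which windows share a topography" rather than "which windows are
#'   equally strong". Set `FALSE` to cluster raw intensities.
#' @return A `cluster_report`: `k_selected`, `labels`,
#'   `component_windows` (tibble), `transition_points_ms`,
#'   `silhouette_by_k` (tibble).
#' @export
cluster_topographies <- function(forward_models, window_centers_ms = NULL,
                                 k_range = 2:6, seed = 1L,
                                 n_restarts = 10, normalize = TRUE) {
  X <- as.matrix(forward_models)
  n_win <- nrow(X)
  if (n_win < max(k_range) + 1) {
    abort("need more windows than the largest candidate k",
          class = "driftdecode_data_error")
  }
  if (all(apply(X, 2, function(col) length(unique(col)) == 1))) {
    abort("no cluster structure: all topographies identical",
          class = "driftdecode_degenerate_error")
  }
  if (normalize) {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) {
      abort("cannot normalize a zero forward model",
            class = "driftdecode_degenerate_error")
    }
    X <- X / nrm
  }
  set.seed(seed)
  dX <- dist(X)
  sil <- vapply(k_range, function(k) {
    cl <- kmeans(X, centers = k, nstart = n_restarts, iter.max = 100)
    mean(cluster::silhouette(cl$cluster, dX)[, "sil_width"])
  }, numeric(1))
  k_selected <- k_range[which.max(sil)]
  set.seed(seed)
  best <- kmeans(X, centers = k_selected, nstart = n_restarts,
                 iter.max = 100)
  labels <- best$cluster

  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  windows <- tibble::tibble(
    cluster = runs$values, start_idx = starts, end_idx = ends)
  transitions_ms <- NULL
  if (!is.null(window_centers_ms)) {
    windows$start_ms <- window_centers_ms[windows$start_idx]
    windows$end_ms <- window_centers_ms[windows$end_idx]
    if (nrow(windows) > 1) {
      transitions_ms <- (window_centers_ms[windows$end_idx[-nrow(windows)]] +
                           window_centers_ms[windows$start_idx[-1]]) / 2
    }
  }
  structure(list(k_selected = k_selected, labels = labels,
                 component_windows = windows,
                 transition_points_ms = transitions_ms,
                 silhouette_by_k = tibble::tibble(k = k_range,
                                                  silhouette = sil)),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k = %d (silhouette %.3f), %d run(s)\n",
              x$k_selected,
              max(x$silhouette_by_k$silhouette),
              nrow(x$component_windows)))
  invisible(x)
}

# bootstrap statistic matrix: reps x windows, resampling subjects with
# replacement; mean path is a single matrix product
boot_stat_matrix <- function(d, n_boot, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  n_subj <- nrow(d)
  idx <- matrix(sample.int(n_subj, n_boot * n_subj, replace = TRUE),
                n_boot, n_subj)
  if (stat == "mean") {
    W <- matrix(0, n_boot, n_subj)
    for (b in seq_len(n_boot)) {
      tb <- tabulate(idx[b, ], nbins = n_subj)
      W[b, ] <- tb / n_subj
    }
    W %*% d
  } else {
    t(apply(idx, 1, function(ii) apply(d[ii, , drop = FALSE], 2, median)))
  }
}

#' Percentile bootstrap of a paired group-level Az difference
#'
#' Compares two matched Az traces (subjects x windows) window by window:
#' subjects are resampled with replacement `n_boot` times, the paired
#' mean difference is recorded per replicate, and the percentile CI
#' (2.5/97.5 at the default `alpha`) is evaluated against zero. A
#' window is significant when the CI excludes 0 — each bound is a 2.5%
#' one-sided test, matching the convention of evaluating the bound
#' nearest zero.
#'
#' @param az_a,az_b Matrices `[n_subjects x n_windows]`, rows matched by
#'   subject (same order).
#' @param n_boot Bootstrap replicates.
#' @param alpha Total CI mass outside the interval (default 0.05).
#' @param seed Integer seed.
#' @param stat Per-replicate statistic, `"mean"` (default) or
#'   `"median"`.
#' @param window_centers_ms Optional window centers for the report.
#' @param min_subjects Minimum number of subjects.
#' @return A `group_diff` object; `tidy()` gives the per-window table.
#' @export
bootstrap_az_difference <- function(az_a, az_b, n_boot = 1000,
                                    alpha = 0.05, seed = 1L,
                                    stat = "mean",
                                    window_centers_ms = NULL,
                                    min_subjects = 5) {
  az_a <- as.matrix(az_a)
  az_b <- as.matrix(az_b)
  if (!all(dim(az_a) == dim(az_b))) {
    abort("az_a and az_b must have matching dimensions (paired subjects)",
          class = "driftdecode_data_error")
  }
  if (nrow(az_a) < min_subjects) {
    abort(paste0("need at least ", min_subjects, " subjects"),
          class = "driftdecode_data_error")
  }
  d <- az_a - az_b
  set.seed(seed)
  boot <- boot_stat_matrix(d, n_boot, stat)
  ci <- apply(boot, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  mean_diff <- colMeans(d)
  sig <- ci[1, ] > 0 | ci[2, ] < 0
  structure(list(mean_diff = mean_diff, ci_low = ci[1, ],
                 ci_high = ci[2, ], sig_mask = sig, diff_matrix = d,
                 window_centers_ms = window_centers_ms,
                 n_boot = n_boot, alpha = alpha, stat = stat,
                 seed = seed),
            class = "group_diff")
}

#' @export
print.group_diff <- function(x, ...) {
  cat(sprintf("<group_diff> %d windows, %d subjects, %d significant\n",
              length(x$mean_diff), nrow(x$diff_matrix), sum(x$sig_mask)))
  invisible(x)
}

#' Data-driven minimum cluster length
#'
#' Null distribution of the maximum run of consecutive significant
#' windows: each permutation shuffles the temporal order of the windows
#' (the same permutation for every subject, so per-window paired
#' differences stay intact), recomputes the bootstrap significance mask
#' and records the largest run of significant windows. The criterion is
#' the 95th percentile of that null, floored at 3 contiguous samples to
#' suppress transient false positives.
#'
#' @inheritParams bootstrap_az_difference
#' @param n_perm Number of temporal permutations.
#' @param n_boot Bootstrap replicates per permutation.
#' @param alpha_cluster Upper tail mass of the null (default 0.05).
#' @param floor_len Minimum admissible criterion (default 3).
#' @return Integer criterion with the null distribution as attribute
#'   `"null_max_sizes"`.
#' @export
max_cluster_null <- function(az_a, az_b, n_perm = 1000, n_boot = 200,
                             alpha = 0.05, alpha_cluster = 0.05,
                             seed = 1L, floor_len = 3) {
  d <- as.matrix(az_a) - as.matrix(az_b)
  n_win <- ncol(d)
  set.seed(seed)
  null_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    dp <- d[, sample.int(n_win), drop = FALSE]
    boot <- boot_stat_matrix(dp, n_boot)
    ci <- apply(boot, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
                names = FALSE)
    sig <- ci[1, ] > 0 | ci[2, ] < 0
    runs <- rle(sig)
    null_max[p] <- if (any(runs$values)) {
      max(runs$lengths[runs$values])
    } else {
      0L
    }
  }
  crit <- max(floor_len,
              as.integer(quantile(null_max, 1 - alpha_cluster, type = 1)))
  structure(as.integer(crit), null_max_sizes = null_max)
}

#' Contiguous significant clusters
#'
#' Maximal runs of `TRUE` of length at least `min_len`, returned as
#' 1-based inclusive `[start, end]` index pairs.
#'
#' @param sig_mask Logical vector.
#' @param min_len Minimum run length (>= 1).
#' @return List of integer pairs `c(start, end)`.
#' @export
find_clusters <- function(sig_mask, min_len = 1) {
  stopifnot(min_len >= 1)
  runs <- rle(as.logical(sig_mask))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_len
  purrr::map2(starts[keep], ends[keep], function(s, e) {
    c(as.integer(s), as.integer(e))
  })
}

#' Participant-level consistency of a cluster effect
#'
#' Fraction of subjects whose mean difference over the cluster's windows
#' shares the sign of the group mean over the same span — a check that a
#' group effect is not driven by a minority of subjects. Undefined
#' (returns `NA`) when the group mean over the cluster is exactly zero.
#'
#' @param diff_per_subject Matrix `[n_subjects x n_windows]` of paired
#'   differences.
#' @param cluster Length-2 inclusive index span `c(start, end)`.
#' @return Proportion in `[0, 1]`, or `NA` when undefined.
#' @export
participant_consistency <- function(diff_per_subject, cluster) {
  d <- as.matrix(diff_per_subject)
  if (cluster[1] < 1 || cluster[2] > ncol(d) || cluster[1] > cluster[2]) {
    abort("cluster span outside the window grid",
          class = "driftdecode_range_error")
  }
  subj_means <- rowMeans(d[, cluster[1]:cluster[2], drop = FALSE])
  g <- mean(subj_means)
  if (g == 0) return(NA_real_)
  mean(sign(subj_means) == sign(g))
}

#' Full group-level comparison of two Az traces
#'
#' Convenience wrapper chaining the percentile bootstrap, the
#' data-driven minimum cluster criterion, cluster extraction, and the
#' participant-consistency proportion per cluster.
#'
#' @inheritParams bootstrap_az_difference
#' @inheritParams max_cluster_null
#' @return A `group_diff` with `min_cluster_len`, `clusters` and a
#'   `consistency` value per cluster added.
#' @export
group_inference <- function(az_a, az_b, n_boot = 1000, n_perm = 1000,
                            alpha = 0.05, alpha_cluster = 0.05,
                            seed = 1L, window_centers_ms = NULL) {
  res <- bootstrap_az_difference(az_a, az_b, n_boot = n_boot,
                                 alpha = alpha, seed = seed,
                                 window_centers_ms = window_centers_ms)
  res$min_cluster_len <- max_cluster_null(az_a, az_b, n_perm = n_perm,
                                          n_boot = min(n_boot, 200),
                                          alpha = alpha,
                                          alpha_cluster = alpha_cluster,
                                          seed = seed + 1L)
  res$clusters <- find_clusters(res$sig_mask, res$min_cluster_len)
  res$consistency <- vapply(res$clusters, function(cl) {
    participant_consistency(res$diff_matrix, cl)
  }, numeric(1))
  # after the cluster criterion, significance is membership in a
  # surviving cluster
  final_mask <- rep(FALSE, length(res$sig_mask))
  for (cl in res$clusters) final_mask[cl[1]:cl[2]] <- TRUE
  res$sig_mask <- final_mask
  res
}
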