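#' Tidy the group-level posterior of a hierarchical fit
#'
#' One row per group-level parameter: posterior mean, SD, 95% credible
#' interval and split-R-hat.
#'
#' @param x An `hddm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hddm_fit
#' @export
tidy.hddm_fit <- function(x, ...) {
  pars <- dimnames(x$group_draws)[[3]]
  rhat <- gelman_rubin(x)
  purrr::map_dfr(pars, function(pn) {
    dr <- as.vector(x$group_draws[, , pn])
    tibble::tibble(
      term = pn, estimate = mean(dr), std.error = sd(dr),
      conf.low = quantile(dr, 0.025, names = FALSE),
      conf.high = quantile(dr, 0.975, names = FALSE),
      rhat = rhat[[pn]]
    )
  })
}

#' One-line summary of a hierarchical fit
#'
#' @param x An `hddm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with model number, data size, DIC and the
#'   worst R-hat.
#' @method glance hddm_fit
#' @export
glance.hddm_fit <- function(x, ...) {
  d <- dic(x)
  tibble::tibble(
    model = x$spec$model,
    n_subjects = length(x$subjects),
    n_chains = x$n_chains,
    n_kept = dim(x$group_draws)[1],
    dic = as.numeric(d),
    p_d = attr(d, "pD"),
    max_rhat = max(gelman_rubin(x))
  )
}

#' Tidy a sliding-window discrimination result
#'
#' @param x A `discriminator_result`.
#' @param ... Unused.
#' @return A tibble with one row per window: center, Az, and the mean
#'   held-out amplitude per class.
#' @method tidy discriminator_result
#' @export
tidy.discriminator_result <- function(x, ...) {
  pos <- x$labels == x$positive
  tibble::tibble(
    window_center_ms = x$window_centers_ms,
    az = x$az,
    mean_y_positive = rowMeans(x$y_out[, pos, drop = FALSE]),
    mean_y_negative = rowMeans(x$y_out[, !pos, drop = FALSE])
  )
}

#' Tidy a group-level Az comparison
#'
#' @param x A `group_diff`.
#' @param ... Unused.
#' @return A tibble with one row per window: mean difference, CI and
#'   significance.
#' @method tidy group_diff
#' @export
tidy.group_diff <- function(x, ...) {
  out <- tibble::tibble(
    window = seq_along(x$mean_diff),
    mean_diff = x$mean_diff, ci_low = x$ci_low, ci_high = x$ci_high,
    significant = x$sig_mask
  )
  if (!is.null(x$window_centers_ms)) {
    out$window_center_ms <- x$window_centers_ms
  }
  out
}

#' Tidy a topography cluster report
#'
#' @param x A `cluster_report`.
#' @param ... Unused.
#' @return The component-window tibble.
#' @method tidy cluster_report
#' @export
tidy.cluster_report <- function(x, ...) x$component_windows

#' Plot a discrimination time course
#'
#' Az against window center with the chance level and, optionally, the
#' permutation threshold.
#'
#' @param object A `discriminator_result`.
#' @param threshold Optional tibble from [permutation_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot discriminator_result
#' @export
autoplot.discriminator_result <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window_center_ms,
                                        y = .data$az)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window center (ms)", y = "Az (leave-one-out)")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_line(
      data = threshold,
      ggplot2::aes(x = .data$window_center_ms, y = .data$threshold),
      linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a group-level Az difference with bootstrap CI
#'
#' @param object A `group_diff`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_diff
#' @export
autoplot.group_diff <- function(object, ...) {
  df <- tidy(object)
  xvar <- if ("window_center_ms" %in% names(df)) {
    "window_center_ms"
  } else {
    "window"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_diff)) +
    ggplot2::geom_point(
      data = df[df$significant, , drop = FALSE],
      ggplot2::aes(y = .data$mean_diff), colour = "red", size = 1) +
    ggplot2::labs(x = xvar, y = "Az difference (a - b)")
}

#' Plot group-level posterior densities
#'
#' @param object An `hddm_fit`.
#' @param parameters Optional subset of group parameter names.
#' @param ... Unused.
#' @return A ggplot object, one facet per parameter.
#' @method autoplot hddm_fit
#' @export
autoplot.hddm_fit <- function(object, parameters = NULL, ...) {
  pars <- dimnames(object$group_draws)[[3]]
  if (!is.null(parameters)) pars <- intersect(pars, parameters)
  df <- purrr::map_dfr(pars, function(pn) {
    tibble::tibble(term = pn,
                   value = as.vector(object$group_draws[, , pn]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "posterior draw", y = "density")
}

#' Plot silhouette values over candidate k
#'
#' @param object A `cluster_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_report
#' @export
autoplot.cluster_report <- function(object, ...) {
  ggplot2::ggplot(object$silhouette_by_k,
                  ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_selected,
                        linetype = "dashed") +
    ggplot2::labs(x = "k", y = "mean silhouette")
}
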