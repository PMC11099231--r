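#' Continuous EEG recordings
#'
#' A `continuous_eeg` is a channels x samples numeric matrix (microvolts)
#' with a sampling rate, channel names and optional 3-d sensor
#' positions. The preprocessing chain — channel selection, average
#' re-referencing, zero-phase Butterworth band-pass, epoching, amplitude
#' rejection — is fully deterministic and applied in that fixed order.
#'
#' @param data Numeric matrix `[n_channels, n_samples]`.
#' @param sfreq_hz Sampling rate (> 0).
#' @param channel_names Character vector (defaults to `E001`, ...).
#' @param positions Optional `n_channels x 3` matrix of sensor positions
#'   (rows named by channel), needed for bad-channel interpolation.
#' @return A `continuous_eeg` object.
#' @export
continuous_eeg <- function(data, sfreq_hz, channel_names = NULL,
                           positions = NULL) {
  stopifnot(is.matrix(data), sfreq_hz > 0)
  if (is.null(channel_names)) {
    channel_names <- sprintf("E%03d", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    abort("channel_names must match the number of rows",
          class = "driftdecode_channel_error")
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(data) || ncol(positions) != 3) {
      abort("positions must be n_channels x 3",
            class = "driftdecode_channel_error")
    }
    rownames(positions) <- channel_names
  }
  rownames(data) <- channel_names
  structure(list(data = data, sfreq_hz = sfreq_hz,
                 channel_names = channel_names, positions = positions),
            class = "continuous_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("<continuous_eeg> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq_hz,
              ncol(x$data) / x$sfreq_hz))
  invisible(x)
}

#' Restrict a recording to a channel subset
#'
#' Keeps only the named channels, in the order given (the emulated
#' pipeline keeps 98 of 128 sensors, dropping the off-scalp ring).
#'
#' @param eeg A [continuous_eeg].
#' @param include Character vector of channel names to keep.
#' @return A [continuous_eeg] with the selected channels.
#' @export
select_channels <- function(eeg, include) {
  unknown <- setdiff(include, eeg$channel_names)
  if (length(unknown) > 0) {
    abort(paste0("unknown channel(s): ", paste(unknown, collapse = ", ")),
          class = "driftdecode_channel_error")
  }
  idx <- match(include, eeg$channel_names)
  continuous_eeg(eeg$data[idx, , drop = FALSE], eeg$sfreq_hz,
                 channel_names = include,
                 positions = if (!is.null(eeg$positions)) {
                   eeg$positions[idx, , drop = FALSE]
                 })
}

#' Re-reference to the channel average
#'
#' Subtracts the cross-channel mean at every sample, so the output's
#' channel mean is exactly zero throughout.
#'
#' @param eeg A [continuous_eeg] with at least 2 channels.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(eeg) {
  if (nrow(eeg$data) < 2) {
    abort("average reference needs at least 2 channels",
          class = "driftdecode_reference_error")
  }
  out <- eeg
  out$data <- sweep(eeg$data, 2, colMeans(eeg$data))
  out
}

#' Zero-phase Butterworth band-pass
#'
#' Fourth-order (by default) Butterworth band-pass applied forward and
#' backward (`signal::filtfilt`), giving zero phase shift at the cost of
#' doubling the effective order. Removes DC and drifts below `low_hz`
#' and everything above `high_hz`.
#'
#' @param eeg A [continuous_eeg].
#' @param low_hz,high_hz Cutoff frequencies, `0 < low < high < sfreq/2`.
#' @param order Filter order of the one-pass design.
#' @return The filtered recording.
#' @export
bandpass_butterworth <- function(eeg, low_hz = 0.5, high_hz = 40,
                                 order = 4) {
  nyq <- eeg$sfreq_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    abort("need 0 < low_hz < high_hz < Nyquist",
          class = "driftdecode_filter_error")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- eeg
  out$data <- t(apply(eeg$data, 1, function(ch) {
    signal::filtfilt(bf, ch)
  }))
  rownames(out$data) <- eeg$channel_names
  out
}

#' Extract stimulus-locked epochs
#'
#' Cuts half-open windows `[tmin_ms, tmax_ms)` around each event marker;
#' at 1,000 Hz the default 1,200 ms window (200 ms pre-stimulus) yields
#' exactly 1,200 samples. Events whose window does not fit inside the
#' recording are skipped with a warning. Epoch data equal the continuous
#' slices exactly — no detrending or baselining is applied here.
#'
#' @param eeg A [continuous_eeg].
#' @param events Integer vector of 1-based event sample indices.
#' @param tmin_ms,tmax_ms Epoch window relative to the event, ms.
#' @param labels Optional condition label per event (recycled `"event"`).
#' @return An [epoch_set].
#' @export
epoch_continuous <- function(eeg, events, tmin_ms = -200, tmax_ms = 1000,
                             labels = NULL) {
  step <- 1000 / eeg$sfreq_hz
  offsets <- round(tmin_ms / step):(round(tmax_ms / step) - 1L)
  n_samples <- length(offsets)
  n_total <- ncol(eeg$data)
  valid <- vapply(events, function(ev) {
    ev + offsets[1] >= 1 && ev + offsets[n_samples] <= n_total
  }, logical(1))
  if (any(!valid)) {
    warn(sprintf("skipping %d event(s) without full epoch margins",
                 sum(!valid)))
  }
  events_kept <- events[valid]
  if (length(events_kept) == 0) {
    abort("no valid events to epoch", class = "driftdecode_epoch_error")
  }
  if (is.null(labels)) labels <- rep("event", length(events))
  labels <- labels[valid]
  data <- array(0, dim = c(length(events_kept), nrow(eeg$data), n_samples))
  for (i in seq_along(events_kept)) {
    data[i, , ] <- eeg$data[, events_kept[i] + offsets, drop = FALSE]
  }
  epoch_set(data, times_ms = offsets * step, labels = labels,
            sfreq_hz = eeg$sfreq_hz, channel_names = eeg$channel_names,
            meta = list(events = events_kept))
}

#' Reject epochs by amplitude
#'
#' Drops every epoch whose absolute amplitude strictly exceeds
#' `limit_uv` anywhere (any channel, any sample); the emulated pipeline
#' uses a +/-120 microvolt criterion. The indices of dropped epochs are
#' attached as `meta$rejected`.
#'
#' @param epochs An [epoch_set].
#' @param limit_uv Rejection limit in microvolts (> 0).
#' @return The cleaned [epoch_set].
#' @export
reject_amplitude <- function(epochs, limit_uv = 120) {
  stopifnot(limit_uv > 0)
  peak <- apply(abs(epochs$data), 1, max)
  drop_idx <- which(peak > limit_uv)
  if (length(drop_idx) == 0) {
    epochs$meta$rejected <- integer(0)
    return(epochs)
  }
  keep <- setdiff(seq_len(dim(epochs$data)[1]), drop_idx)
  if (length(keep) == 0) {
    abort("amplitude rejection removed every epoch",
          class = "driftdecode_epoch_error")
  }
  out <- epoch_set(epochs$data[keep, , , drop = FALSE], epochs$times_ms,
                   epochs$labels[keep], epochs$sfreq_hz,
                   epochs$channel_names, epochs$meta)
  out$meta$rejected <- drop_idx
  out
}

#' Interpolate bad channels
#'
#' Replaces each bad channel by the inverse-distance-weighted mean of
#' its `k` nearest good neighbors (sensor positions required). More than
#' 5% bad channels triggers a warning, mirroring the usual
#' quality-control ceiling.
#'
#' @param eeg A [continuous_eeg] with `positions`.
#' @param bad Character vector of bad channel names.
#' @param k Number of neighbors.
#' @return The recording with bad channels interpolated.
#' @export
interpolate_bad_channels <- function(eeg, bad, k = 4) {
  if (length(bad) == 0) return(eeg)
  unknown <- setdiff(bad, eeg$channel_names)
  if (length(unknown) > 0) {
    abort(paste0("unknown channel(s): ", paste(unknown, collapse = ", ")),
          class = "driftdecode_channel_error")
  }
  if (is.null(eeg$positions)) {
    abort("sensor positions are required for interpolation",
          class = "driftdecode_channel_error")
  }
  good <- setdiff(eeg$channel_names, bad)
  if (length(good) == 0) {
    abort("cannot interpolate: all channels are bad",
          class = "driftdecode_channel_error")
  }
  if (length(bad) / length(eeg$channel_names) > 0.05) {
    warn("more than 5% bad channels; interpolation quality may suffer")
  }
  out <- eeg
  for (ch in bad) {
    dists <- sqrt(rowSums(sweep(eeg$positions[good, , drop = FALSE], 2,
                                eeg$positions[ch, ])^2))
    nb <- good[order(dists)][seq_len(min(k, length(good)))]
    w <- 1 / pmax(dists[order(dists)][seq_len(length(nb))], 1e-12)
    w <- w / sum(w)
    out$data[ch, ] <- as.numeric(w %*% eeg$data[nb, , drop = FALSE])
  }
  out
}
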