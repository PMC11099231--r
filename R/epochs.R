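#' Epoch sets
#'
#' An `epoch_set` holds stimulus-locked EEG epochs: a numeric tensor of
#' dimension trials x channels x samples (microvolts) plus its metadata —
#' the time axis in milliseconds, the sampling rate, channel names and a
#' condition label per trial. Epoch windows are half-open `[tmin, tmax)`,
#' so 1,200 ms at 1,000 Hz is exactly 1,200 samples.
#'
#' @param data Numeric array `[n_trials, n_channels, n_samples]`.
#' @param times_ms Time axis, strictly increasing, length `n_samples`.
#' @param labels Character vector of condition labels, length `n_trials`.
#' @param sfreq_hz Sampling rate in Hz.
#' @param channel_names Character vector, length `n_channels`.
#' @param meta Optional named list of provenance metadata (e.g. the seed).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times_ms, labels, sfreq_hz,
                      channel_names = NULL, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("epoch data must be a 3-d array [trials x channels x samples]",
          class = "driftdecode_container_error")
  }
  d <- dim(data)
  if (d[1] == 0) {
    abort("empty epoch set", class = "driftdecode_container_error")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("E%03d", seq_len(d[2]))
  }
  if (length(times_ms) != d[3]) {
    abort("times_ms length must equal the number of samples",
          class = "driftdecode_container_error")
  }
  if (length(labels) != d[1]) {
    abort("labels length must equal the number of trials",
          class = "driftdecode_container_error")
  }
  if (length(channel_names) != d[2]) {
    abort("channel_names length must equal the number of channels",
          class = "driftdecode_container_error")
  }
  if (any(diff(times_ms) <= 0)) {
    abort("times_ms must be strictly increasing",
          class = "driftdecode_container_error")
  }
  structure(
    list(data = data, times_ms = as.numeric(times_ms),
         labels = as.character(labels), sfreq_hz = as.numeric(sfreq_hz),
         channel_names = as.character(channel_names), meta = meta),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz, %g..%g ms\n",
    d[1], d[2], d[3], x$sfreq_hz, min(x$times_ms), max(x$times_ms)))
  cat("labels:", paste(sprintf("%s (%d)", names(table(x$labels)),
                               table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

EPOCH_MAGIC <- "DRIFTDECODE-EPOCHS-1"

#' Read and write epoch containers
#'
#' Epoch sets are stored in a single self-describing binary file: a magic
#' line, one JSON header line carrying every piece of metadata (dims,
#' channel names, time axis, labels, sampling rate, provenance), then the
#' tensor as little-endian float64 in trial-major order. The container
#' round-trips exactly (`write` then `read` reproduces the tensor and
#' metadata bit for bit).
#'
#' @param epochs An [epoch_set].
#' @param path File path.
#' @return `read_epochs()` returns an [epoch_set].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  header <- jsonlite::toJSON(
    list(dim = dim(epochs$data), times_ms = epochs$times_ms,
         labels = epochs$labels, sfreq_hz = epochs$sfreq_hz,
         channel_names = epochs$channel_names, meta = epochs$meta),
    auto_unbox = FALSE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(EPOCH_MAGIC, as.character(header)), con, sep = "\n")
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "driftdecode_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, EPOCH_MAGIC)) {
    abort("not an epoch container", class = "driftdecode_container_error")
  }
  header <- jsonlite::fromJSON(readLines(con, n = 1L),
                               simplifyVector = TRUE)
  d <- as.integer(header$dim)
  n <- prod(d)
  values <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(values) != n) {
    abort("truncated epoch container: payload shorter than header dims",
          class = "driftdecode_container_error")
  }
  meta <- header$meta
  if (length(meta) == 0) meta <- list()
  epoch_set(array(values, dim = d), times_ms = header$times_ms,
            labels = header$labels, sfreq_hz = header$sfreq_hz,
            channel_names = header$channel_names, meta = as.list(meta))
}

#' Tidy an epoch set into a long tibble
#'
#' One row per trial x channel x sample; mainly useful for plotting small
#' epoch sets.
#'
#' @param x An [epoch_set].
#' @param ... Unused.
#' @method tidy epoch_set
#' @export
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$channel_names, each = d[1]), times = d[3]),
    time_ms = rep(x$times_ms, each = d[1] * d[2]),
    label = rep(x$labels, times = d[2] * d[3]),
    amplitude_uv = as.vector(x$data)
  )
}
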