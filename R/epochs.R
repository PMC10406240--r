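#' Multi-trial EEG epochs
#'
#' Container for segmented multichannel EEG: a numeric array of
#' `trials x channels x samples`, the sampling rate and unique channel
#' labels. All downstream estimators ([estimate_cross_spectra()],
#' [correlation_matrix()]) consume this class.
#'
#' @param data numeric array, `trials x channels x samples`.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names; defaults
#'   to the array's channel dimnames, else `"ch01"`, `"ch02"`, ...
#' @return An object of class `eeg_epochs` with elements `data`, `fs`,
#'   `channel_labels`.
#' @examples
#' x <- array(rnorm(2 * 3 * 64), c(2, 3, 64))
#' ep <- eeg_epochs(x, fs = 128)
#' ep
#' @export
eeg_epochs <- function(data, fs, channel_labels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("`data` must be a 3-D array (trials x channels x samples)")
  }
  d <- dim(data)
  if (d[1L] < 1L) stopf("at least one trial is required")
  if (d[2L] < 2L) stopf("at least two channels are required")
  if (!all(is.finite(data))) stopf("epoch data must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stopf("`fs` must be a positive sampling rate in Hz")
  }
  if (is.null(channel_labels)) channel_labels <- dimnames(data)[[2L]]
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(d[2L]))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != d[2L]) {
    stopf("%d channel labels supplied for %d channels",
          length(channel_labels), d[2L])
  }
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  structure(list(data = data, fs = fs, channel_labels = channel_labels),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("eeg_epochs: %d trial(s) x %d channel(s) x %d sample(s) @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat("channels:", paste(head(x$channel_labels, 8L), collapse = ", "),
      if (d[2L] > 8L) "..." else "", "\n")
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1L]
n_channels <- function(epochs) dim(epochs$data)[2L]
n_samples <- function(epochs) dim(epochs$data)[3L]

#' Write / read epochs as a plain-text container
#'
#' Epochs are stored as two files sharing a prefix: `<prefix>.csv`, the data
#' flattened to `(trials * channels) x samples` (trial-major rows), and
#' `<prefix>.json`, a sidecar recording `fs`, `channel_labels` and the array
#' dimensions. The container is plain text and round-trips exactly at full
#' double precision.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param prefix file path prefix (no extension).
#' @return `write_epochs()` returns `prefix` invisibly; `read_epochs()`
#'   returns an [eeg_epochs()] object.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  flat <- do.call(rbind, lapply(seq_len(d[1L]), function(t) {
    matrix(epochs$data[t, , ], nrow = d[2L], ncol = d[3L])
  }))
  utils::write.table(format(flat, digits = 17, scientific = TRUE, trim = TRUE),
                     paste0(prefix, ".csv"), sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  meta <- list(fs = epochs$fs, channel_labels = epochs$channel_labels,
               n_trials = d[1L], n_channels = d[2L], n_samples = d[3L])
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(prefix, ".csv"), sep = ",",
                                      header = FALSE))
  dat <- array(NA_real_, c(meta$n_trials, meta$n_channels, meta$n_samples))
  for (t in seq_len(meta$n_trials)) {
    rows <- (t - 1L) * meta$n_channels + seq_len(meta$n_channels)
    dat[t, , ] <- flat[rows, , drop = FALSE]
  }
  eeg_epochs(dat, fs = meta$fs, channel_labels = meta$channel_labels)
}
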