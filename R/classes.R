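#' Stimulus feature series
#'
#' Container for a stimulus feature stream sampled at the EEG frame rate:
#' either a one-row speech envelope or a 16-band mel spectrogram. Rows are
#' features, columns are frames.
#'
#' @param values numeric matrix, `n_features x n_frames`.
#' @param fs sampling rate in Hz (128 for the standard analysis).
#' @param name feature name, `"envelope"` or `"spectrogram"` (free-form
#'   names are allowed for derived streams).
#' @return An object of class `feature_series` with fields `values`, `fs`,
#'   `name`, `n_features`, `n_frames`.
#' @export
feature_series <- function(values, fs, name = "spectrogram") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(fs) == 1L, fs > 0)
  structure(
    list(values = values, fs = fs, name = name,
         n_features = nrow(values), n_frames = ncol(values)),
    class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series '%s'> %d feature(s) x %d frames @ %g Hz\n",
              x$name, x$n_features, x$n_frames, x$fs))
  invisible(x)
}

#' Multichannel EEG recording
#'
#' @param data numeric matrix, `n_channels x n_samples`.
#' @param fs sampling rate in Hz.
#' @param band band label: one of `names(eeg_bands())`, `"raw"`, or a
#'   free-form label.
#' @param channel_names optional character vector of channel labels.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, band = "raw", channel_names = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), length(fs) == 1L, fs > 0)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(channel_names) == nrow(data))
  structure(
    list(data = data, fs = fs, band = band, channel_names = channel_names),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, band '%s'\n",
              nrow(x$data), ncol(x$data), x$fs, x$band))
  invisible(x)
}

#' EEG frequency bands of interest
#'
#' The canonical band edges used throughout the analysis: Delta (1-4 Hz),
#' Theta (4-8 Hz), Alpha (8-13 Hz), LowBeta (13-19 Hz) and a broad
#' ERP-style band (0.1-40 Hz).
#'
#' @return Named list of `c(low, high)` band edges in Hz.
#' @export
eeg_bands <- function() {
  list(Delta = c(1, 4), Theta = c(4, 8), Alpha = c(8, 13),
       LowBeta = c(13, 19), Broad = c(0.1, 40))
}
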