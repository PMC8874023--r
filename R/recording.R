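#' Multichannel EEG recording
#'
#' An `eeg_recording` holds a channels-by-samples matrix of potentials in
#' microvolts together with its sampling rate and ordered channel names. It is
#' the container passed between the generator, the cleaning methods, and the
#' evaluation suite.
#'
#' @param data Numeric matrix, channels x samples, in microvolts. Row names are
#'   ignored; channel identity comes from `channel_names`.
#' @param sampling_rate Sampling rate in Hz (default 512).
#' @param channel_names Character vector of channel labels, one per row.
#' @return An `eeg_recording` object.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(1024), nrow = 2), 512, c("Fp1", "Cz"))
#' rec
#' @export
eeg_recording <- function(data, sampling_rate = 512, channel_names = rownames(data)) {
  if (!is.matrix(data) || !is.numeric(data)) {
    value_error("`data` must be a numeric channels x samples matrix.")
  }
  if (any(!is.finite(data))) value_error("recording values must all be finite.")
  assert_scalar_number(sampling_rate, "sampling_rate", min = 1)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data)) {
    size_error("`channel_names` must have one label per data row.")
  }
  if (anyDuplicated(channel_names)) value_error("channel names must be unique.")
  rownames(data) <- channel_names
  structure(
    list(data = data, sampling_rate = sampling_rate, channel_names = channel_names),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
    nrow(x$data), ncol(x$data), x$sampling_rate, ncol(x$data) / x$sampling_rate
  ))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(recording) ncol(recording$data)

channel <- function(recording, name) {
  if (!name %in% recording$channel_names) {
    abort(sprintf("channel '%s' not present in recording.", name),
          class = "blinkclean_key_error")
  }
  recording$data[name, ]
}

#' Convert a recording to a long tibble
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return A tibble with columns `time` (s), `channel` (factor in montage
#'   order), and `value` (microvolts).
#' @method as_tibble eeg_recording
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  t_s <- (seq_len(ncol(x$data)) - 1L) / x$sampling_rate
  tibble(
    time = rep(t_s, each = nrow(x$data)),
    channel = factor(rep(x$channel_names, times = ncol(x$data)), levels = x$channel_names),
    value = as.vector(x$data)
  )
}

#' Plot a recording as stacked channel traces
#'
#' @param object An `eeg_recording`.
#' @param channels Optional subset of channel names to draw.
#' @param ... Unused.
#' @return A ggplot object, one facet row per channel.
#' @method autoplot eeg_recording
#' @export
autoplot.eeg_recording <- function(object, channels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(channels)) df <- dplyr::filter(df, .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "potential [µV]") +
    ggplot2::theme_minimal()
}

# Elementwise combination preserving metadata; used by generator internals.
recording_like <- function(recording, data) {
  eeg_recording(data, recording$sampling_rate, recording$channel_names)
}
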