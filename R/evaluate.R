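#' Evaluate one cleaning method against the known clean recording
#'
#' For every channel, both recordings are cut into consecutive whole 1-s
#' windows; per window the five comparison statistics are computed and then
#' averaged: `c_kk` (Pearson correlation of cleaned with clean), `c_fp1`
#' (correlation of cleaned with the reference signal), `mape` and `rmse`
#' (cleaned vs clean), and `skewness` (of the cleaned signal). Windows where a
#' correlation or skewness is undefined (constant signal) are dropped from
#' that statistic's mean.
#'
#' @param clean The reference clean [eeg_recording()].
#' @param cleaned The method's output [eeg_recording()], aligned with `clean`.
#' @param reference_signal Numeric vector, the (contaminated) reference
#'   channel trace used for `c_fp1`; defaults to the clean recording's Fp1 row
#'   if missing.
#' @param method Label stored in the `method` column.
#' @param window_samples Samples per evaluation window (default: 1 s at the
#'   recording's rate).
#' @return A tibble with one row per channel: `method`, `channel`, `c_kk`,
#'   `c_fp1`, `mape`, `rmse`, `skewness`, `n_windows`.
#' @examples
#' pair <- generate_recording(2, generator_config(), seed = 1)
#' evaluate_method(pair$clean, pair$contaminated,
#'                 pair$contaminated$data["Fp1", ], method = "none")
#' @export
evaluate_method <- function(clean, cleaned, reference_signal = NULL,
                            method = "method",
                            window_samples = round(clean$sampling_rate)) {
  if (!all(dim(clean$data) == dim(cleaned$data)) ||
      !identical(clean$channel_names, cleaned$channel_names)) {
    size_error("`clean` and `cleaned` recordings must be aligned (same shape and channels).")
  }
  if (is.null(reference_signal)) reference_signal <- clean$data[1, ]
  if (length(reference_signal) != n_samples(clean)) {
    size_error("`reference_signal` must be time-aligned with the recordings.")
  }
  n_win <- n_samples(clean) %/% window_samples
  if (n_win == 0L) size_error("recordings are shorter than one evaluation window.")
  used <- n_win * window_samples
  as_windows <- function(x) matrix(x[seq_len(used)], window_samples, n_win)
  R <- as_windows(reference_signal)
  # column-wise (per-window) statistics, vectorized over the windows; windows
  # where a correlation or skewness is undefined become NA and are dropped
  # from that statistic's mean
  col_corr <- function(A, B) {
    ma <- colMeans(A); mb <- colMeans(B)
    cv <- colMeans(A * B) - ma * mb
    va <- colMeans(A^2) - ma^2
    vb <- colMeans(B^2) - mb^2
    out <- cv / sqrt(va * vb)
    out[va <= 0 | vb <= 0] <- NA_real_
    out
  }
  rows <- purrr::map(clean$channel_names, function(ch) {
    Y <- as_windows(clean$data[ch, ])
    Yh <- as_windows(cleaned$data[ch, ])
    keep <- abs(Y) >= 1e-3 # the near-zero MAPE guard
    n_kept <- colSums(keep)
    mape_w <- colSums(abs(Y - Yh) / pmax(abs(Y), 1e-300) * keep) / n_kept
    mape_w[n_kept == 0] <- NA_real_
    mh <- colMeans(Yh)
    m2 <- colMeans(sweep(Yh, 2, mh)^2)
    m3 <- colMeans(sweep(Yh, 2, mh)^3)
    skew_w <- ifelse(m2 > 0, m3 / m2^1.5, NA_real_)
    tibble(
      method = method, channel = ch,
      c_kk = mean(col_corr(Yh, Y), na.rm = TRUE),
      c_fp1 = mean(col_corr(Yh, R), na.rm = TRUE),
      mape = mean(mape_w, na.rm = TRUE),
      rmse = mean(sqrt(colMeans((Y - Yh)^2))),
      skewness = mean(skew_w, na.rm = TRUE),
      n_windows = n_win
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare several cleaning methods on one synthetic recording
#'
#' Runs [evaluate_method()] for every supplied cleaned recording, appends
#' cross-channel means, and collects descriptive statistics (standard
#' deviation and peak-to-peak) of the raw and cleaned signals.
#'
#' @param clean The reference clean [eeg_recording()].
#' @param contaminated The contaminated [eeg_recording()] (used for the
#'   reference trace and the descriptive table).
#' @param cleaned Named list of cleaned recordings, one per method. A method
#'   may instead be a list `list(cleaned = rec, clean = rec)` to supply its own
#'   comparison reference (e.g. ICA results compared in the filtered domain).
#' @param reference_channel Blink reference channel label (default `"Fp1"`).
#' @return A `metric_report`: list with `per_channel` (tibble of the five
#'   statistics per method and channel), `summary` (cross-channel means per
#'   method), and `descriptives` (std and peak-to-peak per method and channel,
#'   including the raw contaminated signal).
#' @examples
#' pair <- generate_recording(2, generator_config(), seed = 1)
#' reg <- regression_clean(pair$contaminated)
#' rep <- compare_methods(pair$clean, pair$contaminated, list(reg = reg$cleaned))
#' rep$summary
#' @export
compare_methods <- function(clean, contaminated, cleaned,
                            reference_channel = "Fp1") {
  if (length(cleaned) == 0L) value_error("`cleaned` must name at least one method.")
  if (is.null(names(cleaned)) || any(names(cleaned) == "")) {
    value_error("`cleaned` must be a named list (method = recording).")
  }
  ref_trace <- channel(contaminated, reference_channel)
  per_channel <- dplyr::bind_rows(purrr::imap(cleaned, function(entry, nm) {
    if (inherits(entry, "eeg_recording")) entry <- list(cleaned = entry, clean = clean)
    evaluate_method(entry$clean, entry$cleaned, ref_trace, method = nm)
  }))
  summary <- per_channel |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(c("c_kk", "c_fp1", "mape", "rmse", "skewness"), mean),
                     n_channels = dplyr::n(), .groups = "drop")
  describe <- function(rec, nm) {
    tibble(
      method = nm,
      channel = rec$channel_names,
      std = unname(apply(rec$data, 1, sd)),
      peak_to_peak = unname(apply(rec$data, 1, peak_to_peak))
    )
  }
  descriptives <- dplyr::bind_rows(
    describe(contaminated, "raw"),
    dplyr::bind_rows(purrr::imap(cleaned, function(entry, nm) {
      rec <- if (inherits(entry, "eeg_recording")) entry else entry$cleaned
      describe(rec, nm)
    }))
  )
  structure(
    list(per_channel = per_channel, summary = summary, descriptives = descriptives,
         reference_channel = reference_channel),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$summary)
  invisible(x)
}

#' Per-channel rows of a metric report
#' @param x A `metric_report`.
#' @param ... Unused.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_channel

#' Cross-channel means of a metric report
#' @param x A `metric_report`.
#' @param ... Unused.
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) x$summary

#' Plot per-channel MAPE (or another statistic) by method
#' @param object A `metric_report`.
#' @param statistic Column to draw (default `"mape"`).
#' @param ... Unused.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, statistic = "mape", ...) {
  df <- object$per_channel
  df$channel <- factor(df$channel, levels = unique(df$channel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data[[statistic]],
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = statistic, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Run and evaluate all three cleaning methods on a synthetic recording
#'
#' Convenience wrapper for the headline comparison: cleans the contaminated
#' recording with the trained network, reference-channel regression, and ICA,
#' and evaluates each against the known clean recording. The ICA output lives
#' in the high-pass-filtered domain; by default it is nevertheless compared
#' against the raw clean recording, like every other method, so that the
#' filter's own signal removal counts against it (see the methods vignette for
#' why this matches how such comparisons are usually reported). Set
#' `ica_reference = "filtered"` to score ICA against the identically filtered
#' clean recording instead.
#'
#' @param pair An [generate_recording()] result.
#' @param model A trained `denoiser`, or `NULL` to skip the network.
#' @param ica_reference `"raw"` (default) or `"filtered"`.
#' @param reference_channel Blink reference channel label.
#' @param ica_cfg An [ica_config()].
#' @return A `metric_report` (see [compare_methods()]).
#' @export
benchmark_methods <- function(pair, model = NULL, reference_channel = "Fp1",
                              ica_cfg = ica_config(seed = 1),
                              ica_reference = c("raw", "filtered")) {
  ica_reference <- match.arg(ica_reference)
  cleaned <- list()
  if (!is.null(model)) {
    cleaned$cnn <- clean_recording(model, pair$contaminated, reference_channel)
  }
  cleaned$reg <- regression_clean(pair$contaminated, reference_channel)$cleaned
  ica_res <- ica_clean(pair$contaminated, reference_channel, ica_cfg)
  if (ica_reference == "filtered") {
    clean_filtered <- highpass_filter(pair$clean, ica_cfg$highpass_cutoff, ica_cfg$filter_order)
    cleaned$ica <- list(cleaned = ica_res$cleaned, clean = clean_filtered)
  } else {
    cleaned$ica <- ica_res$cleaned
  }
  compare_methods(pair$clean, pair$contaminated, cleaned, reference_channel)
}
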