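#' Reference-channel regression artifact removal
#'
#' Removes blink artifacts by subtracting a scaled copy of the reference
#' (Fp1) signal from every other channel. The reference is mean-centered and
#' its auto-covariance scalar `cov = ref %*% ref` computed; for each
#' non-reference channel the mean-centered channel `x` yields the propagation
#' factor `B = cov^-1 * (ref %*% x)`, and the cleaned channel is
#' `x - B * ref` (with its mean restored). The reference channel itself is
#' returned untouched.
#'
#' @param recording An [eeg_recording()] with at least 2 samples.
#' @param reference_channel Reference channel label (default `"Fp1"`).
#' @return A `regression_result`: list with `cleaned` ([eeg_recording()]),
#'   `coefficients` (tibble `channel`, `B`), `cov` (microvolts squared times
#'   samples), `reference_mean`, `channel_means`, `reference_channel`.
#' @examples
#' pair <- generate_recording(2, generator_config(), seed = 1)
#' fit <- regression_clean(pair$contaminated)
#' tidy(fit)
#' @export
regression_clean <- function(recording, reference_channel = "Fp1") {
  if (n_samples(recording) < 2L) size_error("recording needs at least 2 samples.")
  ref_raw <- channel(recording, reference_channel)
  ref_mean <- mean(ref_raw)
  ref <- ref_raw - ref_mean
  cov_ref <- sum(ref * ref)
  if (cov_ref <= 0 || !is.finite(cov_ref)) {
    degenerate_error("the reference channel is constant; propagation factors are undefined.")
  }
  nonref <- setdiff(recording$channel_names, reference_channel)
  out <- recording$data
  means <- setNames(numeric(length(nonref)), nonref)
  B <- setNames(numeric(length(nonref)), nonref)
  for (ch in nonref) {
    x_raw <- recording$data[ch, ]
    mu <- mean(x_raw)
    x <- x_raw - mu
    b <- sum(ref * x) / cov_ref
    out[ch, ] <- x - b * ref + mu
    means[ch] <- mu
    B[ch] <- b
  }
  structure(
    list(
      cleaned = recording_like(recording, out),
      coefficients = tibble(channel = nonref, B = unname(B)),
      cov = cov_ref,
      reference_mean = ref_mean,
      channel_means = means,
      reference_channel = reference_channel
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> reference %s, cov = %.4g\n",
              x$reference_channel, x$cov))
  print(x$coefficients, n = 5)
  invisible(x)
}

#' Per-channel propagation factors of a regression fit
#' @param x A `regression_result`.
#' @param ... Unused.
#' @return Tibble with `channel` and `B`.
#' @method tidy regression_result
#' @export
tidy.regression_result <- function(x, ...) x$coefficients

#' One-row summary of a regression fit
#' @param x A `regression_result`.
#' @param ... Unused.
#' @method glance regression_result
#' @export
glance.regression_result <- function(x, ...) {
  tibble(
    reference_channel = x$reference_channel,
    cov = x$cov,
    n_channels = nrow(x$coefficients),
    n_samples = n_samples(x$cleaned),
    max_abs_B = max(abs(x$coefficients$B))
  )
}

#' Plot regression propagation factors across the montage
#' @param object A `regression_result`.
#' @param ... Unused.
#' @method autoplot regression_result
#' @export
autoplot.regression_result <- function(object, ...) {
  df <- object$coefficients
  df$channel <- factor(df$channel, levels = df$channel)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$B)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "propagation factor B") +
    ggplot2::theme_minimal()
}
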