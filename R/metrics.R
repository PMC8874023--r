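#' Pearson product-moment correlation
#'
#' @param a,b Equal-length numeric signals (length >= 2, neither constant).
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_corr(1:5, c(2, 1, 4, 3, 6))
#' @export
pearson_corr <- function(a, b) {
  if (length(a) != length(b)) size_error("signals must have equal length.")
  if (length(a) < 2L) size_error("signals need at least 2 samples.")
  if (sd(a) == 0 || sd(b) == 0) {
    degenerate_error("correlation is undefined for a constant signal.")
  }
  cor(a, b)
}

#' Mean absolute percentage error between a reference and a cleaned signal
#'
#' Computes `mean(|y - yhat| / |y|)` over samples — the primary cleaning-error
#' statistic, a dimensionless ratio (no x100 factor). Samples whose reference
#' magnitude falls below `guard` microvolts are excluded from the mean to keep
#' the ratio finite; the exclusion count is attached as an attribute.
#'
#' @param y Reference (clean) signal.
#' @param yhat Cleaned signal.
#' @param guard Near-zero denominator threshold in microvolts (default 1e-3).
#' @return The MAPE ratio, with attribute `n_excluded`.
#' @examples
#' mape(c(1, 2, 4), c(2, 2, 2)) # (1 + 0 + 0.5) / 3
#' @export
mape <- function(y, yhat, guard = 1e-3) {
  if (length(y) != length(yhat)) size_error("signals must have equal length.")
  keep <- abs(y) >= guard
  if (!any(keep)) degenerate_error("all reference samples fall below the magnitude guard.")
  out <- mean(abs(y[keep] - yhat[keep]) / abs(y[keep]))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Root mean square error
#'
#' @param y,yhat Equal-length numeric signals.
#' @return `sqrt(mean((y - yhat)^2))` in microvolts.
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(25 / 2)
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) size_error("signals must have equal length.")
  sqrt(mean((y - yhat)^2))
}

#' Moment-based sample skewness
#'
#' The bias-uncorrected third standardized moment `g1 = m3 / m2^(3/2)`. Zero
#' for symmetric data; a blink's one-sided deflection pushes it away from
#' zero.
#'
#' @param x Numeric signal, length >= 3, non-constant.
#' @return Dimensionless skewness.
#' @examples
#' skewness_g1(c(-1, 0, 1))
#' @export
skewness_g1 <- function(x) {
  if (length(x) < 3L) size_error("skewness needs at least 3 samples.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) degenerate_error("skewness is undefined for a constant signal.")
  mean((x - m)^3) / m2^1.5
}

#' One-sided amplitude spectrum
#'
#' @param x Non-empty numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @return Tibble with `frequency` (Hz) and `amplitude` (microvolts), one row
#'   per bin up to the Nyquist frequency (`floor(n/2) + 1` rows).
#' @examples
#' sp <- amplitude_spectrum(sin(2 * pi * 10 * (0:511) / 512), 512)
#' sp$frequency[which.max(sp$amplitude)]
#' @export
amplitude_spectrum <- function(x, sampling_rate = 512) {
  n <- length(x)
  if (n == 0L) value_error("`x` must be non-empty.")
  co <- fft(x)
  half <- n %/% 2L + 1L
  amp <- Mod(co[seq_len(half)]) / n
  # double the interior bins so amplitudes are one-sided
  interior <- 2:(half - 1L)
  if (n > 2L) amp[interior] <- 2 * amp[interior]
  if (n %% 2L == 1L && half > 1L) amp[half] <- 2 * amp[half]
  tibble(
    frequency = (seq_len(half) - 1L) * sampling_rate / n,
    amplitude = amp
  )
}
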