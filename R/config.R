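#' Default 16-channel 10-20 montage
#'
#' The electrode set of the g.USBamp cap used throughout: fronto-polar to
#' occipital. `Fp1` is the blink reference channel (closest to the eye).
#'
#' @return Character vector of 16 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "F9", "F7", "F3", "Fz", "F4", "F8",
    "C3", "Cz", "C4", "P3", "Pz", "P4", "O1", "O2", "Oz")
}

#' Default blink propagation gains
#'
#' Dimensionless per-electrode gains scaling the blink template added to each
#' channel. The topography decays monotonically from the fronto-polar
#' reference (1.0) to the occipital sites (0.1), mirroring how blink artifacts
#' attenuate from front to back of the scalp. Exact per-electrode values are a
#' package choice (see the methods vignette) and are fully configurable.
#'
#' @param channel_names Channel labels to assign gains for.
#' @return Named numeric vector of gains in `[0, 1]`.
#' @export
default_propagation_gains <- function(channel_names = default_montage()) {
  base <- c(
    Fp1 = 1.00, F9 = 0.85,
    F7 = 0.65, F3 = 0.65, Fz = 0.65, F4 = 0.65, F8 = 0.65,
    C3 = 0.40, Cz = 0.40, C4 = 0.40,
    P3 = 0.25, Pz = 0.25, P4 = 0.25,
    O1 = 0.10, O2 = 0.10, Oz = 0.10
  )
  missing <- setdiff(channel_names, names(base))
  if (length(missing)) {
    # unknown labels get a mid-scalp gain
    base[missing] <- 0.4
  }
  base[channel_names]
}

#' Generator configuration
#'
#' Collects every stochastic-generation parameter of the surrogate EEG/EOG
#' generator: the statistics the synthetic signal must satisfy (per-window
#' standard deviation and peak-to-peak range), the spectrum-perturbation and
#' window-stitching bounds, the blink amplitude/interval/width ranges, the
#' montage and its propagation gains, and the seed.
#'
#' @param sampling_rate Sampling rate in Hz (default 512).
#' @param window_samples Samples per generated window; must equal
#'   `sampling_rate` so a window spans exactly 1 s.
#' @param std_range Per-window standard deviation interval, microvolts
#'   (default `c(5, 15)`).
#' @param p2p_range Per-window peak-to-peak interval, microvolts
#'   (default `c(45, 100)`).
#' @param spectrum_jitter Bound on the coefficients added to the reference
#'   spectrum, microvolts (default 2).
#' @param stitch_limit Maximum amplitude jump allowed across a window
#'   boundary, microvolts (default 7).
#' @param blink_amp_range Blink peak amplitude interval, microvolts
#'   (default `c(0, 650)`).
#' @param blink_interval_range Inter-blink onset interval, seconds
#'   (default `c(0.5, 4)`).
#' @param blink_width_range Blink (Gaussian window) duration interval, seconds
#'   (default `c(0.2, 0.4)`).
#' @param channel_names Ordered montage labels (default [default_montage()]).
#' @param propagation_gains Named per-channel gains in `[-1, 1]`
#'   (default [default_propagation_gains()]). The reference channel must have
#'   gain 1.
#' @param gain_jitter Relative jitter applied to non-reference gains per
#'   recording (default 0.2, i.e. +/-20 percent).
#' @param reference_channel Blink reference channel label (default `"Fp1"`).
#' @param seed Optional integer seed recorded into generated artifacts.
#' @return A `generator_config` list.
#' @examples
#' cfg <- generator_config()
#' cfg$std_range
#' @export
generator_config <- function(sampling_rate = 512,
                             window_samples = sampling_rate,
                             std_range = c(5, 15),
                             p2p_range = c(45, 100),
                             spectrum_jitter = 2,
                             stitch_limit = 7,
                             blink_amp_range = c(0, 650),
                             blink_interval_range = c(0.5, 4),
                             blink_width_range = c(0.2, 0.4),
                             channel_names = default_montage(),
                             propagation_gains = default_propagation_gains(channel_names),
                             gain_jitter = 0.2,
                             reference_channel = "Fp1",
                             seed = NULL) {
  assert_scalar_number(sampling_rate, "sampling_rate", min = 1)
  assert_scalar_number(window_samples, "window_samples", min = 2)
  if (window_samples != sampling_rate) {
    value_error("`window_samples` must equal `sampling_rate`: one window spans 1 s.")
  }
  assert_range(std_range, "std_range")
  assert_range(p2p_range, "p2p_range")
  assert_range(blink_amp_range, "blink_amp_range")
  assert_range(blink_interval_range, "blink_interval_range")
  assert_range(blink_width_range, "blink_width_range")
  assert_scalar_number(spectrum_jitter, "spectrum_jitter", min = 0)
  assert_scalar_number(stitch_limit, "stitch_limit", min = 0)
  assert_scalar_number(gain_jitter, "gain_jitter", min = 0)
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names)) value_error("channel names must be unique.")
  if (!reference_channel %in% channel_names) {
    value_error(sprintf("reference channel '%s' must be in `channel_names`.", reference_channel))
  }
  if (is.null(names(propagation_gains))) names(propagation_gains) <- channel_names
  if (!setequal(names(propagation_gains), channel_names)) {
    size_error("`propagation_gains` must be named for exactly the montage channels.")
  }
  propagation_gains <- propagation_gains[channel_names]
  if (any(abs(propagation_gains) > 1)) {
    value_error("propagation gains must lie in [-1, 1].")
  }
  if (abs(propagation_gains[[reference_channel]] - 1) > 1e-12) {
    value_error("the reference channel must have propagation gain 1.0.")
  }
  structure(
    list(
      sampling_rate = sampling_rate,
      window_samples = as.integer(window_samples),
      std_range = std_range,
      p2p_range = p2p_range,
      spectrum_jitter = spectrum_jitter,
      stitch_limit = stitch_limit,
      blink_amp_range = blink_amp_range,
      blink_interval_range = blink_interval_range,
      blink_width_range = blink_width_range,
      channel_names = channel_names,
      propagation_gains = propagation_gains,
      gain_jitter = gain_jitter,
      reference_channel = reference_channel,
      seed = seed
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<generator_config> %g Hz, %d-sample windows\n",
      "  std %g-%g µV, p2p %g-%g µV, jitter ±%g µV, stitch ≤%g µV\n",
      "  blinks: amp %g-%g µV, gap %g-%g s, width %g-%g s\n",
      "  %d channels, reference %s\n"
    ),
    x$sampling_rate, x$window_samples,
    x$std_range[1], x$std_range[2], x$p2p_range[1], x$p2p_range[2],
    x$spectrum_jitter, x$stitch_limit,
    x$blink_amp_range[1], x$blink_amp_range[2],
    x$blink_interval_range[1], x$blink_interval_range[2],
    x$blink_width_range[1], x$blink_width_range[2],
    length(x$channel_names), x$reference_channel
  ))
  invisible(x)
}
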