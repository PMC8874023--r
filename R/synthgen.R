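#' Discrete Fourier spectrum of a reference window
#'
#' Computes the complex DFT coefficients of a single 1-s reference window.
#' The spectrum is the object the surrogate generator perturbs: new clean
#' windows are drawn by adding bounded random coefficients to it and inverse
#' transforming.
#'
#' @param window Numeric vector, one window of a single channel (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @return A `reference_spectrum` with fields `coefficients` (complex, same
#'   length as `window`) and `sampling_rate`.
#' @examples
#' sp <- derive_reference_spectrum(sin(2 * pi * 10 * (0:511) / 512), 512)
#' length(sp$coefficients)
#' @export
derive_reference_spectrum <- function(window, sampling_rate = 512) {
  if (!is.numeric(window) || length(window) < 2L) {
    size_error("`window` must be a numeric vector with at least 2 samples.")
  }
  if (any(!is.finite(window))) value_error("`window` must contain only finite values.")
  assert_scalar_number(sampling_rate, "sampling_rate", min = 1)
  structure(
    list(coefficients = fft(window), sampling_rate = sampling_rate),
    class = "reference_spectrum"
  )
}

#' @export
print.reference_spectrum <- function(x, ...) {
  cat(sprintf("<reference_spectrum> %d coefficients @ %g Hz\n",
              length(x$coefficients), x$sampling_rate))
  invisible(x)
}

# Draw n raw (unscaled) pink-noise windows as a window_samples x n matrix.
# Built in the frequency domain: complex-Gaussian coefficients with amplitude
# proportional to 1/sqrt(f) (power spectral density proportional to 1/f),
# Hermitian-mirrored, inverse transformed.
pink_noise_matrix <- function(n, window_samples, sampling_rate) {
  N <- window_samples
  half <- N %/% 2L # Nyquist index offset; assumes even N
  f <- (1:half) * sampling_rate / N
  amp <- 1 / sqrt(f)
  coef <- matrix(0 + 0i, nrow = N, ncol = n)
  # positive frequencies 1..half-1 complex, Nyquist real
  re <- matrix(rnorm((half - 1L) * n), half - 1L, n) * amp[seq_len(half - 1L)]
  im <- matrix(rnorm((half - 1L) * n), half - 1L, n) * amp[seq_len(half - 1L)]
  coef[2:half, ] <- complex(real = re, imaginary = im)
  coef[half + 1L, ] <- rnorm(n) * amp[half]
  coef[seq(N, half + 2L), ] <- Conj(coef[2:half, , drop = FALSE])
  x <- Re(mvfft(coef, inverse = TRUE)) / N
  x
}

# Rescale columns (about their means) so std and peak-to-peak jointly fall in
# the configured ranges. Columns for which no common scale exists are redrawn.
rescale_into_ranges <- function(x, config, max_attempts = 100L) {
  sds <- apply(x, 2, sd)
  p2p <- apply(x, 2, peak_to_peak)
  lo <- pmax(config$std_range[1] / sds, config$p2p_range[1] / p2p)
  hi <- pmin(config$std_range[2] / sds, config$p2p_range[2] / p2p)
  bad <- which(lo > hi)
  attempts <- 0L
  while (length(bad) && attempts < max_attempts) {
    x[, bad] <- pink_noise_matrix(length(bad), config$window_samples, config$sampling_rate)
    sds[bad] <- apply(x[, bad, drop = FALSE], 2, sd)
    p2p[bad] <- apply(x[, bad, drop = FALSE], 2, peak_to_peak)
    lo[bad] <- pmax(config$std_range[1] / sds[bad], config$p2p_range[1] / p2p[bad])
    hi[bad] <- pmin(config$std_range[2] / sds[bad], config$p2p_range[2] / p2p[bad])
    bad <- bad[lo[bad] > hi[bad]]
    attempts <- attempts + 1L
  }
  if (length(bad)) {
    value_error("could not draw pink windows satisfying both std and peak-to-peak ranges.")
  }
  s <- runif(ncol(x), lo, hi)
  mu <- colMeans(x)
  sweep(sweep(x, 2, mu, "-"), 2, s, "*") + rep(mu, each = nrow(x))
}

#' Surrogate 1/f-noise reference window
#'
#' Draws one 1-s pink-noise (1/f) window rescaled so its standard deviation and
#' peak-to-peak amplitude fall inside the configured ranges. Serves as the
#' reference signal for spectrum perturbation when no real EEG fragment is
#' supplied.
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return Numeric vector of `config$window_samples` microvolt values.
#' @examples
#' w <- pink_reference(generator_config(), seed = 1)
#' sd(w)
#' @export
pink_reference <- function(config = generator_config(), seed = NULL) {
  with_seed_if(seed, {
    x <- pink_noise_matrix(1L, config$window_samples, config$sampling_rate)
    drop(rescale_into_ranges(x, config))
  })
}

# Add bounded uniform perturbations to a matrix of DFT coefficient columns,
# preserving Hermitian symmetry. Returns list(coefficients, max_perturbation).
perturb_spectrum_matrix <- function(coef, jitter) {
  N <- nrow(coef)
  n <- ncol(coef)
  half <- N %/% 2L
  if (jitter == 0) {
    return(list(coefficients = coef, max_perturbation = rep(0, n)))
  }
  k <- half - 1L # strictly positive, non-Nyquist frequencies
  d_re <- matrix(runif(k * n, -jitter, jitter), k, n)
  d_im <- matrix(runif(k * n, -jitter, jitter), k, n)
  d_dc <- runif(n, -jitter, jitter)
  d_ny <- runif(n, -jitter, jitter)
  coef[1L, ] <- coef[1L, ] + d_dc
  coef[2:half, ] <- coef[2:half, ] + complex(real = d_re, imaginary = d_im)
  coef[half + 1L, ] <- coef[half + 1L, ] + d_ny
  coef[seq(N, half + 2L), ] <- Conj(coef[2:half, , drop = FALSE])
  max_pert <- pmax(
    apply(abs(d_re), 2, max), apply(abs(d_im), 2, max),
    abs(d_dc), abs(d_ny)
  )
  list(coefficients = coef, max_perturbation = max_pert)
}

# Inverse-transform perturbed coefficient columns to real windows, checking the
# imaginary residue that Hermitian symmetry should annihilate.
ifft_real <- function(coef, tol = 1e-9) {
  x <- mvfft(coef, inverse = TRUE) / nrow(coef)
  residue <- max(abs(Im(x)))
  if (residue > tol) {
    value_error(sprintf("imaginary residue %.3g exceeds %.1g; spectrum not Hermitian.", residue, tol))
  }
  Re(x)
}

#' Generate one clean surrogate EEG window from a reference spectrum
#'
#' Adds independent uniform perturbations bounded by `config$spectrum_jitter`
#' to the real and imaginary parts of the positive-frequency coefficients
#' (mirrored to keep the spectrum Hermitian), inverse transforms, and enforces
#' the configured std/peak-to-peak ranges: windows are rejection-sampled up to
#' `max_attempts` fresh perturbations, after which the window is linearly
#' rescaled about its mean.
#'
#' @param spectrum A [derive_reference_spectrum()] result (or any object with
#'   complex `coefficients`).
#' @param config A [generator_config()]; `config$window_samples` must equal the
#'   spectrum length.
#' @param seed Optional integer seed.
#' @param max_attempts Rejection attempts before falling back to rescaling.
#' @return Numeric window with attributes `max_perturbation` (largest absolute
#'   random coefficient drawn across all attempts) and `enforcement`
#'   (`"accepted"`, `"rescaled"`, or `"unchecked"` when the jitter is zero and
#'   the reference is returned as-is).
#' @export
generate_clean_window <- function(spectrum, config = generator_config(), seed = NULL,
                                  max_attempts = 100L) {
  coef <- spectrum$coefficients
  if (length(coef) != config$window_samples) {
    size_error(sprintf("spectrum length %d does not match window_samples %d.",
                       length(coef), config$window_samples))
  }
  with_seed_if(seed, {
    if (config$spectrum_jitter == 0) {
      w <- ifft_real(cbind(coef))
      w <- drop(w)
      attr(w, "max_perturbation") <- 0
      attr(w, "enforcement") <- "unchecked"
      return(w)
    }
    max_pert <- 0
    best <- NULL
    for (attempt in seq_len(max_attempts)) {
      pert <- perturb_spectrum_matrix(cbind(coef), config$spectrum_jitter)
      max_pert <- max(max_pert, pert$max_perturbation)
      w <- drop(ifft_real(pert$coefficients))
      s <- sd(w)
      p <- peak_to_peak(w)
      if (s >= config$std_range[1] && s <= config$std_range[2] &&
          p >= config$p2p_range[1] && p <= config$p2p_range[2]) {
        attr(w, "max_perturbation") <- max_pert
        attr(w, "enforcement") <- "accepted"
        return(w)
      }
      best <- w
    }
    # fall back: rescale the last draw about its mean into both ranges
    w <- drop(rescale_into_single_window_ranges(best, config))
    attr(w, "max_perturbation") <- max_pert
    attr(w, "enforcement") <- "rescaled"
    w
  })
}

# Rescale one window about its mean so std and p2p fall inside the configured
# ranges; if no common scale exists, satisfy the std range (its midpoint).
rescale_into_single_window_ranges <- function(w, config) {
  s0 <- sd(w)
  p0 <- peak_to_peak(w)
  lo <- max(config$std_range[1] / s0, config$p2p_range[1] / p0)
  hi <- min(config$std_range[2] / s0, config$p2p_range[2] / p0)
  s <- if (lo <= hi) (lo + hi) / 2 else mean(config$std_range) / s0
  mean(w) + (w - mean(w)) * s
}

#' Generate a batch of clean surrogate windows
#'
#' Vectorized form of [generate_clean_window()]: each window gets a fresh
#' pink-noise reference (drawn inside the configured ranges) whose spectrum is
#' then perturbed by the bounded random coefficients. Windows pushed out of the
#' std/peak-to-peak ranges by the perturbation are re-enforced individually.
#'
#' @param n Number of 1-s windows.
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return `window_samples` x `n` matrix with attribute `max_perturbation`
#'   (per-window largest absolute random coefficient drawn).
#' @examples
#' w <- generate_clean_windows(3, generator_config(), seed = 1)
#' dim(w)
#' @export
generate_clean_windows <- function(n, config = generator_config(), seed = NULL) {
  assert_scalar_number(n, "n", min = 0)
  n <- as.integer(n)
  if (n == 0L) {
    out <- matrix(numeric(0), nrow = config$window_samples, ncol = 0)
    attr(out, "max_perturbation") <- numeric(0)
    return(out)
  }
  with_seed_if(seed, {
    ref <- pink_noise_matrix(n, config$window_samples, config$sampling_rate)
    ref <- rescale_into_ranges(ref, config)
    pert <- perturb_spectrum_matrix(mvfft(ref), config$spectrum_jitter)
    x <- ifft_real(pert$coefficients)
    max_pert <- pert$max_perturbation
    sds <- apply(x, 2, sd)
    p2p <- apply(x, 2, peak_to_peak)
    bad <- which(sds < config$std_range[1] | sds > config$std_range[2] |
                   p2p < config$p2p_range[1] | p2p > config$p2p_range[2])
    for (j in bad) {
      w <- generate_clean_window(derive_reference_spectrum(ref[, j], config$sampling_rate),
                                 config)
      max_pert[j] <- max(max_pert[j], attr(w, "max_perturbation"))
      x[, j] <- as.numeric(w)
    }
    attr(x, "max_perturbation") <- max_pert
    x
  })
}

#' Stitch 1-s windows into a continuous signal
#'
#' Concatenates windows in order, offsetting each incoming window vertically by
#' the minimal amount needed so that the amplitude jump across every boundary
#' stays within `config$stitch_limit` (the jump is clamped to the limit;
#' windows already within the limit are left untouched).
#'
#' @param windows A `window_samples` x n matrix or a list of equal-length
#'   numeric windows.
#' @param config A [generator_config()].
#' @return Numeric vector of length `n * window_samples`.
#' @examples
#' w <- generate_clean_windows(4, generator_config(), seed = 1)
#' x <- stitch_windows(w)
#' length(x)
#' @export
stitch_windows <- function(windows, config = generator_config()) {
  if (is.list(windows)) {
    if (length(windows) == 0L) value_error("`windows` must contain at least one window.")
    len <- lengths(windows)
    if (any(len != len[1])) size_error("all windows must have equal length.")
    windows <- matrix(unlist(windows), nrow = len[1])
  }
  if (!is.matrix(windows) || ncol(windows) == 0L) {
    value_error("`windows` must contain at least one window.")
  }
  n <- ncol(windows)
  if (n == 1L) return(drop(windows[, 1L]))
  out <- windows
  last <- out[nrow(out), 1L]
  for (k in 2:n) {
    jump <- out[1L, k] - last
    if (abs(jump) > config$stitch_limit) {
      # clamp the boundary jump to just inside the limit (guards rounding)
      out[, k] <- out[, k] - (jump - sign(jump) * config$stitch_limit * (1 - 1e-9))
    }
    last <- out[nrow(out), k]
  }
  as.vector(out)
}

#' Gaussian-window blink template
#'
#' The eye-blink artifact is modeled as a Gaussian window: a symmetric pulse
#' whose peak sample equals `amplitude` and whose support spans `width`
#' seconds (the envelope decays to ~1 percent of the peak at the edges).
#'
#' @param amplitude Peak amplitude in microvolts (>= 0).
#' @param width Blink duration in seconds (> 0).
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric vector of odd length covering `width` seconds.
#' @examples
#' b <- blink_waveform(100, 0.3, 512)
#' max(b)
#' @export
blink_waveform <- function(amplitude, width, sampling_rate = 512) {
  assert_scalar_number(amplitude, "amplitude", min = 0)
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0) {
    value_error("`width` must be a single positive number of seconds.")
  }
  assert_scalar_number(sampling_rate, "sampling_rate", min = 1)
  L <- round(width * sampling_rate)
  if (L %% 2 == 0) L <- L + 1 # odd length so the peak lands on a sample
  if (L < 3) L <- 3
  centre <- (L - 1) / 2
  sigma <- (L - 1) / 6 # edges at 3 sigma
  i <- 0:(L - 1)
  amplitude * exp(-0.5 * ((i - centre) / sigma)^2)
}

#' Sample a train of blink events
#'
#' Blink onsets are generated by accumulating inter-blink gaps drawn uniformly
#' from `config$blink_interval_range`; amplitudes are uniform in
#' `config$blink_amp_range` and widths uniform in `config$blink_width_range`.
#' Events whose onset falls beyond `duration` are discarded.
#'
#' @param duration Signal duration in seconds (>= 0).
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return A `blink_train` tibble with columns `onset` (s), `amplitude`
#'   (microvolts), and `width` (s).
#' @examples
#' sample_blink_train(10, generator_config(), seed = 1)
#' @export
sample_blink_train <- function(duration, config = generator_config(), seed = NULL) {
  assert_scalar_number(duration, "duration", min = 0)
  with_seed_if(seed, {
    # expected count + slack; draw in one batch then trim
    n_guess <- max(8L, ceiling(duration / mean(config$blink_interval_range) * 1.6) + 8L)
    onsets <- numeric(0)
    t_last <- 0
    repeat {
      gaps <- runif(n_guess, config$blink_interval_range[1], config$blink_interval_range[2])
      new <- t_last + cumsum(gaps)
      onsets <- c(onsets, new)
      t_last <- onsets[length(onsets)]
      if (t_last >= duration) break
    }
    onsets <- onsets[onsets < duration]
    n <- length(onsets)
    events <- tibble(
      onset = onsets,
      amplitude = runif(n, config$blink_amp_range[1], config$blink_amp_range[2]),
      width = runif(n, config$blink_width_range[1], config$blink_width_range[2])
    )
    class(events) <- c("blink_train", class(events))
    attr(events, "duration") <- duration
    attr(events, "seed") <- seed
    events
  })
}

#' Render a blink train as a single-channel signal
#'
#' @param train A [sample_blink_train()] tibble.
#' @param duration Signal duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric vector of `duration * sampling_rate` samples containing the
#'   summed Gaussian blink templates (truncated at the signal edges).
#' @export
blink_signal <- function(train, duration, sampling_rate = 512) {
  n <- round(duration * sampling_rate)
  x <- numeric(n)
  if (nrow(train) == 0L || n == 0L) return(x)
  for (i in seq_len(nrow(train))) {
    w <- blink_waveform(train$amplitude[i], train$width[i], sampling_rate)
    start <- round(train$onset[i] * sampling_rate) + 1L
    idx <- start:(start + length(w) - 1L)
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + w[keep]
  }
  x
}

#' Propagate a blink signal across channels
#'
#' Multiplies the single-channel blink signal by the per-channel gain vector,
#' producing the channels x samples artifact matrix that is added to the clean
#' recording ("appropriate amplification or attenuation" per electrode).
#'
#' @param blink_signal Numeric vector, the reference-channel blink trace.
#' @param gains Numeric per-channel gain vector (optionally named).
#' @return `length(gains)` x `length(blink_signal)` matrix; row `c` equals
#'   `gains[c] * blink_signal`.
#' @examples
#' propagate_blinks(c(0, 1, 0.5), c(Fp1 = 1, Cz = 0.4))
#' @export
propagate_blinks <- function(blink_signal, gains) {
  if (!is.numeric(blink_signal) || !is.numeric(gains)) {
    value_error("`blink_signal` and `gains` must be numeric.")
  }
  if (length(gains) == 0L) size_error("`gains` must contain at least one channel gain.")
  out <- outer(as.numeric(gains), as.numeric(blink_signal))
  rownames(out) <- names(gains)
  out
}

# Generate one channel of continuous clean EEG: stitched spectrum-jittered
# windows. The boundary constraint is met by redrawing the incoming window —
# implemented as a scan over a pre-drawn pool of i.i.d. candidate windows —
# and, should no candidate fit, by the minimal DC offset of stitch_windows().
generate_channel <- function(n_windows, config, max_refills = 100L) {
  if (n_windows == 1L) return(drop(generate_clean_windows(1L, config)[, 1L]))
  pool <- generate_clean_windows(max(2L * n_windows, n_windows + 8L), config)
  used <- logical(ncol(pool))
  first_samples <- pool[1L, ]
  out <- matrix(0, nrow(pool), n_windows)
  take <- function(idx) {
    used[idx] <<- TRUE
    pool[, idx]
  }
  out[, 1L] <- take(1L)
  last <- out[nrow(out), 1L]
  for (k in 2:n_windows) {
    fit <- which(!used & abs(first_samples - last) <= config$stitch_limit)
    refills <- 0L
    while (length(fit) == 0L && refills < max_refills) {
      extra <- generate_clean_windows(16L, config)
      pool <- cbind(pool, extra)
      used <- c(used, logical(16L))
      first_samples <- c(first_samples, extra[1L, ])
      fit <- which(!used & abs(first_samples - last) <= config$stitch_limit)
      refills <- refills + 1L
    }
    if (length(fit)) {
      out[, k] <- take(fit[1L])
    } else {
      idx <- which(!used)[1L]
      w <- take(idx)
      jump <- w[1L] - last
      out[, k] <- w - (jump - sign(jump) * config$stitch_limit * (1 - 1e-9))
    }
    last <- out[nrow(out), k]
  }
  as.vector(out)
}

#' Generate a paired clean/contaminated multichannel recording
#'
#' Builds per-channel clean EEG from stitched spectrum-jittered windows, draws
#' one blink train, propagates it across the montage with the configured gains
#' (non-reference gains jittered by `config$gain_jitter` per recording and
#' clamped below the reference's 1.0), and returns the clean recording, the
#' contaminated recording (clean + artifact), the blink train, and the exact
#' artifact matrix.
#'
#' @param duration Recording duration in whole seconds.
#' @param config A [generator_config()].
#' @param seed Optional integer seed (recorded in the result).
#' @return An `eeg_recording_pair`: list with elements `clean`, `contaminated`
#'   (both [eeg_recording()]), `blinks` (blink train tibble), `artifact`
#'   (channels x samples matrix), `gains`, `config`, `seed`.
#' @examples
#' pair <- generate_recording(2, generator_config(), seed = 1)
#' pair$contaminated
#' @export
generate_recording <- function(duration, config = generator_config(), seed = NULL) {
  assert_scalar_number(duration, "duration", min = 1)
  if (abs(duration - round(duration)) > 1e-9) {
    value_error("`duration` must be a whole number of seconds.")
  }
  duration <- as.integer(round(duration))
  with_seed_if(seed, {
    nch <- length(config$channel_names)
    clean <- matrix(0, nrow = nch, ncol = duration * config$window_samples)
    for (c in seq_len(nch)) {
      clean[c, ] <- generate_channel(duration, config)
    }
    train <- sample_blink_train(duration, config)
    blink <- blink_signal(train, duration, config$sampling_rate)
    gains <- config$propagation_gains
    ref <- config$reference_channel
    jit <- runif(nch, 1 - config$gain_jitter, 1 + config$gain_jitter)
    gains_j <- gains * jit
    gains_j[ref] <- 1.0 # the reference carries the full-amplitude artifact
    nonref <- setdiff(config$channel_names, ref)
    gains_j[nonref] <- pmin(abs(gains_j[nonref]), 0.99) * sign(gains_j[nonref] + (gains_j[nonref] == 0))
    artifact <- propagate_blinks(blink, gains_j)
    clean_rec <- eeg_recording(clean, config$sampling_rate, config$channel_names)
    contaminated_rec <- recording_like(clean_rec, clean + artifact)
    structure(
      list(
        clean = clean_rec,
        contaminated = contaminated_rec,
        blinks = train,
        artifact = artifact,
        gains = gains_j,
        config = config,
        seed = seed
      ),
      class = "eeg_recording_pair"
    )
  })
}

#' @export
print.eeg_recording_pair <- function(x, ...) {
  cat(sprintf("<eeg_recording_pair> %d channels x %d samples @ %g Hz, %d blinks\n",
              nrow(x$clean$data), ncol(x$clean$data), x$clean$sampling_rate, nrow(x$blinks)))
  invisible(x)
}

#' Generate a paired-window training dataset
#'
#' Emits `n_windows` aligned examples for the convolutional denoiser. Each
#' example pairs the synchronous 1-s windows of (reference channel with blinks,
#' contaminated target channel) with the clean target window, cycling over all
#' non-reference channels of internally generated recordings. Examples are
#' shuffled and an 80/20 train/validation split is recorded in the metadata.
#'
#' @param n_windows Number of examples (default 70000).
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @param recording_duration Duration in seconds of each internal source
#'   recording (default 60).
#' @param train_fraction Fraction of examples labeled `"train"` (default 0.8).
#' @return A `paired_window_dataset`: list with matrices `ref`, `contaminated`,
#'   `target`, `ref_clean` (each n x window_samples), a `metadata` tibble
#'   (`example`, `recording`, `window`, `channel`, `gain`, `split`), plus
#'   `config` and `seed`.
#' @examples
#' ds <- generate_dataset(30, generator_config(), seed = 1, recording_duration = 2)
#' table(ds$metadata$split)
#' @export
generate_dataset <- function(n_windows = 70000, config = generator_config(), seed = NULL,
                             recording_duration = 60, train_fraction = 0.8) {
  assert_scalar_number(n_windows, "n_windows", min = 0)
  n_windows <- as.integer(n_windows)
  ws <- config$window_samples
  nonref <- setdiff(config$channel_names, config$reference_channel)
  per_rec <- length(nonref) * recording_duration
  if (n_windows == 0L) {
    empty <- matrix(numeric(0), nrow = 0, ncol = ws)
    return(structure(
      list(ref = empty, contaminated = empty, target = empty, ref_clean = empty,
           metadata = tibble(example = integer(0), recording = integer(0),
                             window = integer(0), channel = character(0),
                             gain = numeric(0), split = character(0)),
           config = config, seed = seed),
      class = "paired_window_dataset"
    ))
  }
  with_seed_if(seed, {
    n_rec <- ceiling(n_windows / per_rec)
    pool <- n_rec * per_rec
    ref <- matrix(0, pool, ws)
    ref_clean <- matrix(0, pool, ws)
    contaminated <- matrix(0, pool, ws)
    target <- matrix(0, pool, ws)
    meta_rec <- integer(pool); meta_win <- integer(pool)
    meta_ch <- character(pool); meta_gain <- numeric(pool)
    row <- 0L
    for (r in seq_len(n_rec)) {
      pair <- generate_recording(recording_duration, config)
      ref_con <- pair$contaminated$data[config$reference_channel, ]
      ref_cln <- pair$clean$data[config$reference_channel, ]
      for (k in seq_len(recording_duration)) {
        idx <- ((k - 1L) * ws + 1L):(k * ws)
        for (ch in nonref) {
          row <- row + 1L
          ref[row, ] <- ref_con[idx]
          ref_clean[row, ] <- ref_cln[idx]
          contaminated[row, ] <- pair$contaminated$data[ch, idx]
          target[row, ] <- pair$clean$data[ch, idx]
          meta_rec[row] <- r; meta_win[row] <- k
          meta_ch[row] <- ch; meta_gain[row] <- pair$gains[[ch]]
        }
      }
    }
    keep <- sample.int(pool, n_windows)
    n_train <- floor(n_windows * train_fraction)
    split <- c(rep("train", n_train), rep("validation", n_windows - n_train))
    structure(
      list(
        ref = ref[keep, , drop = FALSE],
        contaminated = contaminated[keep, , drop = FALSE],
        target = target[keep, , drop = FALSE],
        ref_clean = ref_clean[keep, , drop = FALSE],
        metadata = tibble(
          example = seq_len(n_windows),
          recording = meta_rec[keep],
          window = meta_win[keep],
          channel = meta_ch[keep],
          gain = meta_gain[keep],
          split = split
        ),
        config = config,
        seed = seed
      ),
      class = "paired_window_dataset"
    )
  })
}

#' @export
print.paired_window_dataset <- function(x, ...) {
  n <- nrow(x$ref)
  cat(sprintf("<paired_window_dataset> %d examples x %d samples (%d train / %d validation)\n",
              n, ncol(x$ref), sum(x$metadata$split == "train"),
              sum(x$metadata$split == "validation")))
  invisible(x)
}

#' Number of examples in a paired-window dataset
#' @param x A `paired_window_dataset`.
#' @export
n_examples <- function(x) nrow(x$ref)
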