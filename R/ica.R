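#' Zero-phase Butterworth high-pass filter
#'
#' Applies an order-`order` Butterworth high-pass filter forward and backward
#' (zero phase, squared magnitude response) to every channel. Used to remove
#' slow drifts before ICA decomposition (cutoff 1 Hz, order 6 by default).
#'
#' @param recording An [eeg_recording()].
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param order Filter order (default 6).
#' @return The filtered [eeg_recording()].
#' @examples
#' pair <- generate_recording(2, generator_config(), seed = 1)
#' filtered <- highpass_filter(pair$contaminated)
#' @export
highpass_filter <- function(recording, cutoff = 1, order = 6) {
  assert_scalar_number(cutoff, "cutoff", min = .Machine$double.xmin)
  nyquist <- recording$sampling_rate / 2
  if (cutoff >= nyquist) {
    value_error(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz.", cutoff, nyquist))
  }
  bf <- signal::butter(order, cutoff / nyquist, type = "high")
  out <- t(apply(recording$data, 1, function(x) signal::filtfilt(bf, x)))
  recording_like(recording, out)
}

#' ICA configuration
#'
#' @param n_components Number of retained components (default 15).
#' @param highpass_cutoff High-pass cutoff in Hz applied before decomposition
#'   (default 1).
#' @param filter_order Butterworth order (default 6).
#' @param n_remove Number of blink components to remove (default 2).
#' @param max_iterations Fixed-point iteration cap (default 1000).
#' @param tolerance Convergence tolerance on the unmixing update (default 1e-4).
#' @param seed Integer seed for the random orthogonal initialization.
#' @return An `ica_config` list.
#' @export
ica_config <- function(n_components = 15, highpass_cutoff = 1, filter_order = 6,
                       n_remove = 2, max_iterations = 1000, tolerance = 1e-4,
                       seed = NULL) {
  assert_scalar_number(n_components, "n_components", min = 1)
  assert_scalar_number(n_remove, "n_remove", min = 0)
  if (n_remove > n_components) value_error("`n_remove` cannot exceed `n_components`.")
  structure(
    list(n_components = as.integer(n_components), highpass_cutoff = highpass_cutoff,
         filter_order = filter_order, n_remove = as.integer(n_remove),
         max_iterations = as.integer(max_iterations), tolerance = tolerance, seed = seed),
    class = "ica_config"
  )
}

# symmetric decorrelation W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps))) %*% t(e$vectors) %*% W
}

#' FastICA decomposition of a multichannel recording
#'
#' Estimates statistically independent sources by the fixed-point (FastICA)
#' iteration with the log-cosh contrast: channels are mean-removed, whitened by
#' PCA retaining `n_components` principal directions, and the orthogonal
#' unmixing matrix is iterated with symmetric decorrelation from a seeded
#' random start. Non-convergence within `max_iterations` is recorded in the
#' model (`converged`), not raised.
#'
#' The caller is expected to high-pass filter the recording first (see
#' [highpass_filter()]), or use [ica_clean()] which does both.
#'
#' @param recording An [eeg_recording()] with at least `n_components` channels.
#' @param config An [ica_config()].
#' @return An `ica_model`: list with `unmixing` (components x channels),
#'   `mixing` (channels x components), `sources` (components x samples,
#'   zero mean), `channel_means`, `converged`, `iterations`, `config`.
#' @examples
#' pair <- generate_recording(2, generator_config(), seed = 1)
#' model <- ica_decompose(highpass_filter(pair$contaminated), ica_config(seed = 1))
#' dim(model$sources)
#' @export
ica_decompose <- function(recording, config = ica_config()) {
  X <- recording$data
  p <- nrow(X)
  if (p < config$n_components) {
    size_error(sprintf("recording has %d channels but %d components were requested.",
                       p, config$n_components))
  }
  n <- ncol(X)
  means <- rowMeans(X)
  Xc <- X - means
  # PCA whitening, keep n_components directions
  C <- tcrossprod(Xc) / n
  e <- eigen(C, symmetric = TRUE)
  k <- config$n_components
  K <- diag(1 / sqrt(e$values[seq_len(k)]), k) %*% t(e$vectors[, seq_len(k), drop = FALSE])
  Z <- K %*% Xc # k x n, identity covariance
  with_seed_if(config$seed, {
    W <- sym_decorrelate(matrix(rnorm(k * k), k, k))
    converged <- FALSE
    iterations <- config$max_iterations
    for (it in seq_len(config$max_iterations)) {
      WZ <- W %*% Z
      G <- tanh(WZ)              # derivative of log cosh
      Gp <- 1 - G^2
      W_new <- sym_decorrelate(tcrossprod(G, Z) / n - diag(rowMeans(Gp)) %*% W)
      delta <- 1 - min(abs(diag(W_new %*% t(W)))) # rotation of each row
      W <- W_new
      if (delta < config$tolerance) {
        converged <- TRUE
        iterations <- it
        break
      }
    }
    if (!converged) {
      warn(sprintf("FastICA did not converge within %d iterations.", config$max_iterations))
    }
    unmixing <- W %*% K                                    # k x p
    mixing <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k) %*% t(W)         # p x k, pseudo-inverse
    sources <- W %*% Z
    structure(
      list(unmixing = unmixing, mixing = mixing, sources = sources,
           channel_means = means, channel_names = recording$channel_names,
           sampling_rate = recording$sampling_rate,
           converged = converged, iterations = iterations, config = config),
      class = "ica_model"
    )
  })
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("<ica_model> %d components over %d channels, %s after %d iterations\n",
              nrow(x$sources), length(x$channel_names),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Rank ICA components by correlation with a blink reference signal
#'
#' Automatic stand-in for visual component selection: components are ranked by
#' the absolute Pearson correlation of their source row with the reference
#' signal (typically the filtered Fp1 trace) and the top `n_remove` indices
#' are returned.
#'
#' @param model An [ica_decompose()] result.
#' @param reference_signal Numeric vector time-aligned with the sources.
#' @param n_remove Number of components to select (default from the model's
#'   config).
#' @return Integer vector of component indices, highest correlation first.
#' @export
select_blink_components <- function(model, reference_signal,
                                    n_remove = model$config$n_remove) {
  k <- nrow(model$sources)
  if (n_remove > k) value_error("`n_remove` cannot exceed the number of components.")
  if (length(reference_signal) != ncol(model$sources)) {
    size_error("`reference_signal` must be time-aligned with the sources.")
  }
  if (n_remove == 0L) return(integer(0))
  r <- abs(apply(model$sources, 1, function(s) {
    if (sd(s) == 0 || sd(reference_signal) == 0) 0 else cor(s, reference_signal)
  }))
  order(r, decreasing = TRUE)[seq_len(n_remove)]
}

#' Reconstruct a recording from an ICA model with components removed
#'
#' Zeroes the removed components' columns of the mixing matrix (the modified
#' mixing matrix), remixes the remaining sources, and restores the channel
#' means.
#'
#' @param model An [ica_decompose()] result.
#' @param remove Integer component indices to drop (possibly empty).
#' @return The reconstructed [eeg_recording()].
#' @export
ica_reconstruct <- function(model, remove = integer(0)) {
  k <- nrow(model$sources)
  remove <- as.integer(remove)
  if (length(remove) && (any(remove < 1L) || any(remove > k))) {
    value_error(sprintf("component indices must lie in 1..%d.", k))
  }
  mixing_mod <- model$mixing
  mixing_mod[, remove] <- 0
  X <- mixing_mod %*% model$sources + model$channel_means
  eeg_recording(X, model$sampling_rate, model$channel_names)
}

#' Full ICA cleaning pipeline
#'
#' High-pass filters the recording, decomposes it into independent components,
#' selects the `n_remove` components most correlated with the (filtered)
#' reference channel, and reconstructs without them. Note the returned
#' recording lives in the filtered domain; comparisons against a clean
#' reference should filter that reference identically (see
#' [benchmark_methods()]).
#'
#' @param recording An [eeg_recording()].
#' @param reference_channel Blink reference channel label (default `"Fp1"`).
#' @param config An [ica_config()].
#' @return List with `cleaned` ([eeg_recording()], filtered domain), `model`
#'   (the `ica_model`), and `removed` (component indices).
#' @export
ica_clean <- function(recording, reference_channel = "Fp1", config = ica_config()) {
  filtered <- highpass_filter(recording, config$highpass_cutoff, config$filter_order)
  model <- ica_decompose(filtered, config)
  removed <- select_blink_components(model, channel(filtered, reference_channel))
  list(cleaned = ica_reconstruct(model, removed), model = model, removed = removed)
}

#' Component-wise summary of an ICA model
#' @param x An `ica_model`.
#' @param ... Unused.
#' @return Tibble with one row per component: index, source variance, and the
#'   channel whose mixing weight is largest.
#' @method tidy ica_model
#' @export
tidy.ica_model <- function(x, ...) {
  tibble(
    component = seq_len(nrow(x$sources)),
    variance = apply(x$sources, 1, stats::var),
    top_channel = x$channel_names[apply(abs(x$mixing), 2, which.max)]
  )
}

#' One-row summary of an ICA model
#' @param x An `ica_model`.
#' @param ... Unused.
#' @method glance ica_model
#' @export
glance.ica_model <- function(x, ...) {
  tibble(
    n_components = nrow(x$sources),
    n_channels = length(x$channel_names),
    converged = x$converged,
    iterations = x$iterations
  )
}
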