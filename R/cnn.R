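#' Architecture of the two-channel convolutional denoiser
#'
#' Fixes the layer stack of the blink-removal network: a (512, 2) input window
#' (reference channel, contaminated channel), a 1-D convolution with 20
#' kernels of length 40 and stride 2 ("same" padding, ReLU), a 1-D convolution
#' with 10 kernels of length 20 and stride 1 ("same" padding, ReLU), a flatten
#' layer, and a dense linear output of 512 values (the clean window). No
#' batch-normalization layers are used.
#'
#' @param window_samples Samples per window (default 512).
#' @param sampling_rate Sampling rate the network is trained for (default 512).
#' @return A `denoiser_spec` list describing the layers.
#' @examples
#' model_spec()
#' @export
model_spec <- function(window_samples = 512, sampling_rate = 512) {
  assert_scalar_number(window_samples, "window_samples", min = 8)
  structure(
    list(
      window_samples = as.integer(window_samples),
      sampling_rate = sampling_rate,
      in_channels = 2L,
      conv1 = list(filters = 20L, kernel = 40L, stride = 2L, padding = "same", activation = "relu"),
      conv2 = list(filters = 10L, kernel = 20L, stride = 1L, padding = "same", activation = "relu"),
      dense = as.integer(window_samples)
    ),
    class = "denoiser_spec"
  )
}

#' @export
print.denoiser_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<denoiser_spec> input (%d, %d)\n",
           "  conv1d %d filters x %d, stride %d, same, relu -> %d\n",
           "  conv1d %d filters x %d, stride %d, same, relu -> %d\n",
           "  flatten -> dense %d (linear)\n"),
    x$window_samples, x$in_channels,
    x$conv1$filters, x$conv1$kernel, x$conv1$stride, conv_out_len(x$window_samples, x$conv1$stride),
    x$conv2$filters, x$conv2$kernel, x$conv2$stride,
    conv_out_len(conv_out_len(x$window_samples, x$conv1$stride), x$conv2$stride),
    x$dense
  ))
  invisible(x)
}

#' Output length of a "same"-padded strided convolution
#'
#' @param len Input length.
#' @param stride Stride.
#' @return `ceiling(len / stride)`.
#' @export
conv_out_len <- function(len, stride) as.integer(ceiling(len / stride))

# "same" padding split for a given input length / kernel / stride
same_padding <- function(len, kernel, stride) {
  out <- conv_out_len(len, stride)
  total <- max((out - 1L) * stride + kernel - len, 0L)
  c(left = total %/% 2L, right = total - total %/% 2L)
}

glorot_uniform <- function(fan_in, fan_out, n) {
  limit <- sqrt(6 / (fan_in + fan_out))
  runif(n, -limit, limit)
}

#' Build an untrained denoiser
#'
#' Initializes the network of [model_spec()] with Glorot-uniform weights and
#' zero biases.
#'
#' @param spec A [model_spec()].
#' @param seed Optional integer seed for the weight initialization.
#' @return A `denoiser` object holding the weight matrices.
#' @examples
#' net <- build_denoiser(model_spec(), seed = 1)
#' dim(predict_windows(net, matrix(0, 1, 512), matrix(0, 1, 512)))
#' @export
build_denoiser <- function(spec = model_spec(), seed = NULL) {
  if (!inherits(spec, "denoiser_spec")) {
    abort("`spec` must be a model_spec().", class = "blinkclean_config_error")
  }
  ws <- spec$window_samples
  c1 <- spec$conv1; c2 <- spec$conv2
  l1 <- conv_out_len(ws, c1$stride)
  p1_in <- c1$kernel * spec$in_channels
  p2_in <- c2$kernel * c1$filters
  flat <- conv_out_len(l1, c2$stride) * c2$filters
  with_seed_if(seed, {
    weights <- list(
      W1 = matrix(glorot_uniform(p1_in, c1$kernel * c1$filters, p1_in * c1$filters),
                  p1_in, c1$filters),
      b1 = numeric(c1$filters),
      W2 = matrix(glorot_uniform(p2_in, c2$kernel * c2$filters, p2_in * c2$filters),
                  p2_in, c2$filters),
      b2 = numeric(c2$filters),
      Wd = matrix(glorot_uniform(flat, spec$dense, flat * spec$dense), flat, spec$dense),
      bd = numeric(spec$dense)
    )
    structure(list(spec = spec, weights = weights, seed = seed), class = "denoiser")
  })
}

#' @export
print.denoiser <- function(x, ...) {
  n_par <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf("<denoiser> %s, %d parameters\n",
              if (is.null(x$history)) "untrained" else
                sprintf("trained %d epochs", nrow(x$history)), n_par))
  print(x$spec)
  invisible(x)
}

# --- im2col forward/backward -------------------------------------------------
# Batch layout: row-major over examples; patch matrices are (n * positions) x
# (kernel * channels) with rows ordered position-major (all examples for
# position 1, then position 2, ...). Flattening is channel-major, which lets
# the (n*positions) x filters activation matrix be reinterpreted as the
# n x (positions*filters) dense input without copying structure.

# patches for the strided input convolution; x_ref/x_con are n x ws
conv1_patches <- function(x_ref, x_con, spec) {
  ws <- spec$window_samples
  k <- spec$conv1$kernel
  stride <- spec$conv1$stride
  n <- nrow(x_ref)
  out <- conv_out_len(ws, stride)
  pad <- same_padding(ws, k, stride)
  padded_len <- ws + pad[1] + pad[2]
  starts <- (seq_len(out) - 1L) * stride + 1L
  pad_mat <- function(x) {
    xp <- matrix(0, n, padded_len)
    xp[, (pad[1] + 1L):(pad[1] + ws)] <- x
    xp
  }
  xr <- pad_mat(x_ref); xc <- pad_mat(x_con)
  P <- matrix(0, n * out, 2L * k)
  for (j in seq_len(k)) {
    P[, j] <- as.vector(xr[, starts + j - 1L])
    P[, k + j] <- as.vector(xc[, starts + j - 1L])
  }
  P
}

# The stride-1 second convolution never materializes its patch matrix: in the
# position-major layout a tap offset is a row shift of the whole activation,
# so the convolution is a sum over taps of shifted matrix products. W2 rows
# are ordered channel-major: row (c-1)*kernel + j holds channel c, tap j.

conv2_tap_rows <- function(spec) {
  k <- spec$conv2$kernel
  ch <- spec$conv1$filters
  lapply(seq_len(k), function(j) seq.int(j, by = k, length.out = ch))
}

conv2_forward <- function(A, n, spec, W2, b2) {
  k <- spec$conv2$kernel
  len <- nrow(A)
  pad <- same_padding(len %/% n, k, 1L)
  taps <- conv2_tap_rows(spec)
  Z <- matrix(b2, len, spec$conv2$filters, byrow = TRUE)
  for (j in seq_len(k)) {
    s <- (j - 1L - pad[1]) * n # source row offset for tap j
    d1 <- max(1L, 1L - s); d2 <- min(len, len - s)
    Z[d1:d2, ] <- Z[d1:d2, ] + A[(d1 + s):(d2 + s), , drop = FALSE] %*%
      W2[taps[[j]], , drop = FALSE]
  }
  Z
}

conv2_backward <- function(A, dZ, n, spec, W2) {
  k <- spec$conv2$kernel
  len <- nrow(A)
  pad <- same_padding(len %/% n, k, 1L)
  taps <- conv2_tap_rows(spec)
  dA <- matrix(0, len, ncol(A))
  dW2 <- matrix(0, nrow(W2), ncol(W2))
  for (j in seq_len(k)) {
    s <- (j - 1L - pad[1]) * n
    d1 <- max(1L, 1L - s); d2 <- min(len, len - s)
    src <- (d1 + s):(d2 + s)
    dst <- d1:d2
    dW2[taps[[j]], ] <- crossprod(A[src, , drop = FALSE], dZ[dst, , drop = FALSE])
    dA[src, ] <- dA[src, ] + dZ[dst, , drop = FALSE] %*% t(W2[taps[[j]], , drop = FALSE])
  }
  list(dA = dA, dW2 = dW2)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# forward pass; returns prediction and the intermediates needed for backprop
denoiser_forward <- function(model, x_ref, x_con, keep = FALSE) {
  spec <- model$spec
  w <- model$weights
  n <- nrow(x_ref)
  P1 <- conv1_patches(x_ref, x_con, spec)
  Z1 <- add_bias(P1 %*% w$W1, w$b1)
  A1 <- pmax(Z1, 0)
  Z2 <- conv2_forward(A1, n, spec, w$W2, w$b2)
  A2 <- pmax(Z2, 0)
  FL <- A2
  dim(FL) <- c(n, length(A2) %/% n) # channel-major flatten
  Y <- add_bias(FL %*% w$Wd, w$bd)
  if (!keep) return(list(Y = Y))
  list(Y = Y, P1 = P1, Z1 = Z1, A1 = A1, Z2 = Z2, FL = FL, n = n)
}

denoiser_backward <- function(model, fwd, dY) {
  w <- model$weights
  n <- fwd$n
  dWd <- crossprod(fwd$FL, dY)
  dbd <- colSums(dY)
  dFL <- tcrossprod(dY, w$Wd)
  dA2 <- dFL
  dim(dA2) <- dim(fwd$Z2)
  dZ2 <- dA2 * (fwd$Z2 > 0)
  db2 <- colSums(dZ2)
  conv2_grads <- conv2_backward(fwd$A1, dZ2, n, model$spec, w$W2)
  dZ1 <- conv2_grads$dA * (fwd$Z1 > 0)
  dW1 <- crossprod(fwd$P1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = conv2_grads$dW2, b2 = db2, Wd = dWd, bd = dbd)
}

#' Predict clean windows for a batch of paired input windows
#'
#' @param model A `denoiser` (trained or untrained).
#' @param x_ref n x window_samples matrix of reference-channel windows.
#' @param x_con n x window_samples matrix of contaminated target windows.
#' @param chunk Examples per forward chunk (memory bound).
#' @return n x window_samples matrix of denoised windows.
#' @export
predict_windows <- function(model, x_ref, x_con, chunk = 512L) {
  if (!is.matrix(x_ref)) x_ref <- matrix(x_ref, nrow = 1)
  if (!is.matrix(x_con)) x_con <- matrix(x_con, nrow = 1)
  if (!all(dim(x_ref) == dim(x_con))) size_error("reference and contaminated batches must match.")
  if (ncol(x_ref) != model$spec$window_samples) {
    size_error(sprintf("windows must have %d samples.", model$spec$window_samples))
  }
  n <- nrow(x_ref)
  out <- matrix(0, n, ncol(x_ref))
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j, ] <- denoiser_forward(model, x_ref[i:j, , drop = FALSE],
                                   x_con[i:j, , drop = FALSE])$Y
    i <- j + 1L
  }
  out
}

#' Training configuration for the denoiser
#'
#' ADAM with the published hyperparameters: learning rate 0.001, beta1 0.9,
#' beta2 0.999, epsilon 1e-07; mean-squared-error loss; minibatches of 128;
#' 10 epochs; an 80/20 train/validation split (carried by the dataset).
#'
#' @param learning_rate,beta1,beta2,epsilon ADAM parameters.
#' @param batch_size Minibatch size (default 128).
#' @param epochs Training epochs (default 10).
#' @param seed Integer seed for shuffling (and weight init when the model is
#'   built by [train_denoiser()] itself). Default 20220211.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-07, batch_size = 128, epochs = 10,
                         seed = 20220211) {
  for (nm in c("learning_rate", "beta1", "beta2", "epsilon", "batch_size", "epochs")) {
    assert_scalar_number(get(nm), nm, min = .Machine$double.xmin)
  }
  structure(
    list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         epsilon = epsilon, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = seed),
    class = "train_config"
  )
}

mse_loss <- function(Y, T) mean((Y - T)^2)

#' Train the convolutional denoiser
#'
#' Minimizes the mean squared error between predicted and clean windows with
#' ADAM over minibatches, for the configured number of epochs. Uses the
#' train/validation split recorded in the dataset metadata; per-epoch train and
#' validation losses are kept in the returned history.
#'
#' @param model A [build_denoiser()] result, or `NULL` to build one from
#'   `config$seed`.
#' @param dataset A [generate_dataset()] result (non-empty).
#' @param config A [train_config()].
#' @return A trained `denoiser` with elements `history` (tibble: `epoch`,
#'   `train_loss`, `validation_loss`), `train_config`, and `seed`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(60, generator_config(), seed = 1, recording_duration = 2)
#' net <- train_denoiser(NULL, ds, train_config(epochs = 1, seed = 7))
#' net$history
#' }
#' @export
train_denoiser <- function(model, dataset, config = train_config()) {
  if (n_examples(dataset) == 0L) value_error("`dataset` must contain at least one example.")
  if (is.null(model)) model <- build_denoiser(model_spec(ncol(dataset$ref)), seed = config$seed)
  if (ncol(dataset$ref) != model$spec$window_samples) {
    size_error("dataset window length does not match the model spec.")
  }
  train_idx <- which(dataset$metadata$split == "train")
  val_idx <- which(dataset$metadata$split == "validation")
  if (length(train_idx) == 0L) train_idx <- seq_len(n_examples(dataset))
  w <- model$weights
  m <- lapply(w, function(x) x * 0)
  v <- lapply(w, function(x) x * 0)
  step <- 0L
  history <- tibble(epoch = integer(0), train_loss = numeric(0), validation_loss = numeric(0))
  val_loss <- function() {
    if (length(val_idx) == 0L) return(NA_real_)
    pred <- predict_windows(model, dataset$ref[val_idx, , drop = FALSE],
                            dataset$contaminated[val_idx, , drop = FALSE])
    mse_loss(pred, dataset$target[val_idx, , drop = FALSE])
  }
  with_seed_if(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample(train_idx)
      batch_losses <- numeric(0)
      i <- 1L
      while (i <= length(order_idx)) {
        j <- min(i + config$batch_size - 1L, length(order_idx))
        b <- order_idx[i:j]
        fwd <- denoiser_forward(model, dataset$ref[b, , drop = FALSE],
                                dataset$contaminated[b, , drop = FALSE], keep = TRUE)
        T_mat <- dataset$target[b, , drop = FALSE]
        batch_losses <- c(batch_losses, mse_loss(fwd$Y, T_mat))
        dY <- 2 * (fwd$Y - T_mat) / length(T_mat)
        grads <- denoiser_backward(model, fwd, dY)
        step <- step + 1L
        corr1 <- 1 - config$beta1^step
        corr2 <- 1 - config$beta2^step
        for (nm in names(w)) {
          m[[nm]] <- config$beta1 * m[[nm]] + (1 - config$beta1) * grads[[nm]]
          v[[nm]] <- config$beta2 * v[[nm]] + (1 - config$beta2) * grads[[nm]]^2
          w[[nm]] <- w[[nm]] - config$learning_rate * (m[[nm]] / corr1) /
            (sqrt(v[[nm]] / corr2) + config$epsilon)
        }
        model$weights <- w
        i <- j + 1L
      }
      history <- dplyr::bind_rows(history, tibble(
        epoch = epoch, train_loss = mean(batch_losses), validation_loss = val_loss()
      ))
    }
  })
  model$history <- history
  model$train_config <- config
  model$seed <- config$seed
  model
}

#' Loss history of a trained denoiser
#'
#' @param x A trained `denoiser`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `validation_loss`.
#' @method tidy denoiser
#' @export
tidy.denoiser <- function(x, ...) {
  if (is.null(x$history)) value_error("model has no training history yet.")
  x$history
}

#' One-row training summary of a trained denoiser
#' @param x A trained `denoiser`.
#' @param ... Unused.
#' @method glance denoiser
#' @export
glance.denoiser <- function(x, ...) {
  h <- tidy(x)
  tibble(
    epochs = nrow(h),
    batch_size = x$train_config$batch_size,
    learning_rate = x$train_config$learning_rate,
    final_train_loss = h$train_loss[nrow(h)],
    final_validation_loss = h$validation_loss[nrow(h)],
    seed = x$seed %||% NA_integer_
  )
}

#' Plot the training loss history
#' @param object A trained `denoiser`.
#' @param ... Unused.
#' @method autoplot denoiser
#' @export
autoplot.denoiser <- function(object, ...) {
  h <- tidy(object) |>
    tidyr::pivot_longer(c("train_loss", "validation_loss"),
                        names_to = "set", values_to = "mse")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$mse, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "MSE [µV²]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Remove blink artifacts from a recording with a trained denoiser
#'
#' Splits every non-reference channel into consecutive 1-s windows, pairs each
#' with the synchronous reference-channel window, replaces it with the network
#' output, and reassembles the recording. The reference channel passes through
#' unchanged. A trailing partial window is zero-padded for prediction and the
#' output truncated to the original length.
#'
#' @param model A trained `denoiser`.
#' @param recording An [eeg_recording()] at the model's sampling rate.
#' @param reference_channel Reference channel label (default `"Fp1"`).
#' @return The cleaned [eeg_recording()].
#' @export
clean_recording <- function(model, recording, reference_channel = "Fp1") {
  if (!inherits(model, "denoiser")) value_error("`model` must be a denoiser.")
  if (recording$sampling_rate != model$spec$sampling_rate) {
    value_error(sprintf("recording rate %g Hz does not match the model's %g Hz.",
                        recording$sampling_rate, model$spec$sampling_rate))
  }
  ref_sig <- channel(recording, reference_channel) # key error if absent
  ws <- model$spec$window_samples
  ns <- n_samples(recording)
  n_win <- ceiling(ns / ws)
  padded <- n_win * ws
  pad_vec <- function(x) c(x, numeric(padded - ns))
  ref_windows <- matrix(pad_vec(ref_sig), ncol = ws, byrow = TRUE)
  nonref <- setdiff(recording$channel_names, reference_channel)
  out <- recording$data
  if (length(nonref)) {
    con <- do.call(rbind, lapply(nonref, function(ch) {
      matrix(pad_vec(recording$data[ch, ]), ncol = ws, byrow = TRUE)
    }))
    ref_rep <- ref_windows[rep(seq_len(n_win), times = length(nonref)), , drop = FALSE]
    pred <- predict_windows(model, ref_rep, con)
    for (k in seq_along(nonref)) {
      rows <- ((k - 1L) * n_win + 1L):(k * n_win)
      out[nonref[k], ] <- as.vector(t(pred[rows, , drop = FALSE]))[seq_len(ns)]
    }
  }
  recording_like(recording, out)
}

#' Save / load a trained denoiser
#'
#' `save_denoiser()` serializes the model (weights, spec, training config,
#' history, seed) to an RDS container and writes a JSON sidecar describing the
#' architecture. `load_denoiser()` restores it and verifies the payload;
#' predictions after a round trip are bit-identical.
#'
#' @param model A `denoiser`.
#' @param path Destination file (`.rds`).
#' @return `save_denoiser()` returns `path` invisibly; `load_denoiser()`
#'   returns the restored `denoiser`.
#' @export
save_denoiser <- function(model, path) {
  if (!inherits(model, "denoiser")) value_error("`model` must be a denoiser.")
  saveRDS(model, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(class = "denoiser", spec = model$spec[c("window_samples", "sampling_rate", "dense")],
         trained = !is.null(model$history), seed = model$seed),
    sidecar, auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname save_denoiser
#' @param expected_spec Optional [model_spec()]; loading a model whose
#'   architecture differs raises a format error.
#' @export
load_denoiser <- function(path, expected_spec = NULL) {
  model <- tryCatch(readRDS(path), error = function(e) {
    format_error(sprintf("'%s' is not a readable model file: %s", path, conditionMessage(e)))
  })
  if (!inherits(model, "denoiser") || is.null(model$weights)) {
    format_error(sprintf("'%s' does not contain a denoiser.", path))
  }
  if (!is.null(expected_spec) && !identical(unclass(model$spec), unclass(expected_spec))) {
    format_error("model architecture does not match the expected spec.")
  }
  model
}
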