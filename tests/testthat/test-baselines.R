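make_recording <- function(rows, names, fs = 512) {
  eeg_recording(do.call(rbind, rows), fs, names)
}

test_that("regression recovers known propagation factors exactly", {
  n <- 1000
  t_i <- seq_len(n)
  ref <- sin(2 * pi * 5 * t_i / n) * 50          # blink-reference stand-in
  clean <- cos(2 * pi * 20 * t_i / n) * 10       # orthogonal over full periods

  # closed-form normal-equation oracle on the toy pair
  b_oracle <- function(ref, x) {
    rc <- ref - mean(ref); xc <- x - mean(x)
    sum(rc * xc) / sum(rc * rc)
  }

  # orthogonal target -> B = 0 and the channel is unchanged
  rec <- make_recording(list(ref, clean), c("Fp1", "Cz"))
  fit <- regression_clean(rec)
  expect_equal(fit$coefficients$B, b_oracle(ref, clean), tolerance = 1e-12)
  expect_lt(abs(fit$coefficients$B), 1e-10)
  expect_equal(fit$cleaned$data["Cz", ], clean, tolerance = 1e-9)

  # contaminated = clean + 0.4 * ref -> recovered B = 0.4
  rec2 <- make_recording(list(ref, clean + 0.4 * ref), c("Fp1", "Cz"))
  fit2 <- regression_clean(rec2)
  expect_equal(fit2$coefficients$B, 0.4, tolerance = 1e-6)
  expect_equal(fit2$coefficients$B, b_oracle(ref, clean + 0.4 * ref), tolerance = 1e-12)

  # exact recovery: RMSE of the cleaned channel against the clean one
  expect_lt(rmse(clean, fit2$cleaned$data["Cz", ]), 1e-6)
  # the reference channel is untouched
  expect_identical(fit2$cleaned$data["Fp1", ], ref)

  expect_error(regression_clean(make_recording(list(rep(1, n), clean), c("Fp1", "Cz"))),
               class = "blinkclean_degenerate_error")
})

test_that("regression-cleaned channels are numerically orthogonal to the reference", {
  pair <- generate_recording(10, test_config(), seed = 61)
  fit <- regression_clean(pair$contaminated)
  ref <- pair$contaminated$data["Fp1", ]
  rc <- ref - mean(ref)
  for (ch in setdiff(pair$contaminated$channel_names, "Fp1")) {
    x <- fit$cleaned$data[ch, ]
    xc <- x - mean(x)
    # inner product bounded relative to the norms (least-squares residual)
    expect_lt(abs(sum(rc * xc)), 1e-6 * sqrt(sum(rc^2)) * sqrt(sum(xc^2)))
    expect_lt(abs(pearson_corr(x, ref)), 1e-3)
  }
})

test_that("the zero-phase Butterworth high-pass matches its analytic response", {
  fs <- 512
  t_s <- (0:(20 * fs - 1)) / fs
  mid <- (5 * fs):(15 * fs) # steady-state section away from edge transients

  zero <- eeg_recording(matrix(0, 1, length(t_s)), fs, "Cz")
  expect_equal(max(abs(highpass_filter(zero)$data)), 0)

  # analytic zero-phase magnitude: |H(f)|^2 with |H(f)|^2 = 1/(1+(fc/f)^(2k))
  # for a high-pass Butterworth of order k
  gain2 <- function(f, fc = 1, k = 6) 1 / (1 + (fc / f)^(2 * k))

  slow <- eeg_recording(matrix(sin(2 * pi * 0.1 * t_s) * 100, 1), fs, "Cz")
  slow_out <- highpass_filter(slow)$data[1, mid]
  expect_lt(max(abs(slow_out)) / 100, 1e-3) # >= 10^3 attenuation at 0.1 Hz
  expect_lt(gain2(0.1), 1e-3) # the analytic response demands at least as much

  fast <- eeg_recording(matrix(sin(2 * pi * 10 * t_s) * 100, 1), fs, "Cz")
  fast_out <- highpass_filter(fast)$data[1, mid]
  expect_equal(max(abs(fast_out)) / 100, 1, tolerance = 0.01) # 10 Hz passes within 1 %
  expect_equal(gain2(10), 1, tolerance = 1e-6)

  dc <- eeg_recording(matrix(50 + sin(2 * pi * 10 * t_s), 1), fs, "Cz")
  dc_out <- highpass_filter(dc)$data[1, mid]
  expect_lt(max(abs(dc_out - sin(2 * pi * 10 * t_s)[mid])), 0.5) # 50 uV offset removed

  # idempotence in band: refiltering a filtered 10 Hz sine changes < 2 %
  once <- highpass_filter(fast)
  twice <- highpass_filter(once)
  expect_lt(abs(max(abs(twice$data[1, mid])) - max(abs(once$data[1, mid]))) /
              max(abs(once$data[1, mid])), 0.02)

  expect_error(highpass_filter(zero, cutoff = 300), class = "blinkclean_value_error")
})

test_that("FastICA separates a seeded blink mixture and reconstructs linearly", {
  mix <- make_blink_mixture()
  cfg3 <- ica_config(n_components = 3, n_remove = 1, seed = 2)
  model <- ica_decompose(mix$recording, cfg3)
  expect_true(model$converged)

  # exhaustive correlation scan: some component recovers the blink source
  cors <- abs(apply(model$sources, 1, cor, y = mix$blink))
  expect_gt(max(cors), 0.95)

  # automatic selection returns the argmax of that scan
  sel <- select_blink_components(model, mix$blink, 1)
  expect_identical(sel, which.max(cors))
  expect_identical(select_blink_components(model, mix$blink, 0), integer(0))

  # removing the blink component lowers blink correlation on every channel
  cleaned <- ica_reconstruct(model, sel)
  for (ch in 1:3) {
    expect_lt(abs(cor(cleaned$data[ch, ], mix$blink)),
              abs(cor(mix$recording$data[ch, ], mix$blink)))
  }

  # linear consistency on this small instance: reconstruction equals the
  # zeroed-column mixing matrix times sources plus means
  Am <- model$mixing
  Am[, sel] <- 0
  expect_equal(cleaned$data,
               unname(Am %*% model$sources + model$channel_means),
               ignore_attr = TRUE, tolerance = 1e-10)

  expect_error(ica_reconstruct(model, 7), class = "blinkclean_value_error")
})

test_that("ICA with nothing removed almost reproduces a 16-channel recording", {
  pair <- generate_recording(8, test_config(), seed = 62)
  filtered <- highpass_filter(pair$contaminated)
  cfg <- ica_config(seed = 3)
  expect_identical(cfg$n_components, 15L) # default for the 16-channel montage
  # the surrogate channels are close to uncorrelated, so the Gaussian
  # subspace has no unique rotation and the fixed point may not settle;
  # that is recorded in the model, not raised
  model <- suppressWarnings(ica_decompose(filtered, cfg))
  back <- ica_reconstruct(model, integer(0))
  rel_err <- norm(back$data - filtered$data, "F") / norm(filtered$data, "F")
  # the no-removal reconstruction error is exactly the PCA truncation
  # residual: the energy share of the dropped 16th principal direction
  Xc <- filtered$data - rowMeans(filtered$data)
  ev <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE, only.values = TRUE)$values
  oracle <- sqrt(ev[16] * ncol(Xc)) / norm(filtered$data, "F")
  expect_equal(rel_err, oracle, tolerance = 1e-6)
  expect_lt(rel_err, 0.15)

  # removing everything leaves only the restored channel means
  none <- ica_reconstruct(model, seq_len(15))
  expect_equal(none$data, matrix(rowMeans(filtered$data), 16, ncol(filtered$data)),
               ignore_attr = TRUE, tolerance = 1e-9)

  # default blink selection returns exactly two components
  removed <- select_blink_components(model, channel(filtered, "Fp1"))
  expect_length(removed, 2L)

  expect_error(ica_decompose(eeg_recording(matrix(rnorm(512 * 3), 3), 512,
                                           c("a", "b", "c")), ica_config()),
               class = "blinkclean_size_error")
})
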