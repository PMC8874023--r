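test_that("the network has the published shape contracts", {
  spec <- model_spec()
  # feature length after the strided first convolution: same padding on 512
  # samples with stride 2 gives ceiling(512 / 2) positions
  expect_identical(conv_out_len(spec$window_samples, spec$conv1$stride), 256L)
  expect_identical(conv_out_len(256L, spec$conv2$stride), 256L)

  net <- build_denoiser(spec, seed = 1)
  one <- predict_windows(net, matrix(rnorm(512), 1), matrix(rnorm(512), 1))
  expect_equal(dim(one), c(1L, 512L)) # batch of one, 512 output values

  # weight shapes follow the layer stack (20x40 conv, 10x20 conv, dense 512)
  expect_equal(dim(net$weights$W1), c(40L * 2L, 20L))
  expect_equal(dim(net$weights$W2), c(20L * 20L, 10L))
  expect_equal(dim(net$weights$Wd), c(256L * 10L, 512L))

  expect_error(build_denoiser(list(bogus = TRUE)), class = "blinkclean_config_error")
  expect_error(predict_windows(net, matrix(0, 1, 100), matrix(0, 1, 100)),
               class = "blinkclean_size_error")
})

test_that("analytic gradients match finite differences on a tiny network", {
  spec <- model_spec(32)
  net <- build_denoiser(spec, seed = 3)
  withr::with_seed(42, {
    n <- 3
    xr <- matrix(rnorm(n * 32), n)
    xc <- matrix(rnorm(n * 32), n)
    tg <- matrix(rnorm(n * 32), n)
  })
  fwd <- blinkclean:::denoiser_forward(net, xr, xc, keep = TRUE)
  dY <- 2 * (fwd$Y - tg) / length(tg)
  gr <- blinkclean:::denoiser_backward(net, fwd, dY)
  loss <- function(m) mean((blinkclean:::denoiser_forward(m, xr, xc)$Y - tg)^2)
  eps <- 1e-6
  withr::with_seed(7, {
    for (nm in names(net$weights)) {
      w <- net$weights[[nm]]
      idx <- sample(length(w), min(5, length(w)))
      for (i in idx) {
        m1 <- net; m1$weights[[nm]][i] <- w[i] + eps
        m2 <- net; m2$weights[[nm]][i] <- w[i] - eps
        num <- (loss(m1) - loss(m2)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("training reduces the loss on a degenerate no-artifact task", {
  # contaminated already equals the target: the network only has to learn to
  # reproduce its second input channel
  ds <- generate_dataset(640, test_config(), seed = 9, recording_duration = 4)
  ds$contaminated <- ds$target
  ds$ref <- ds$ref_clean
  net <- train_denoiser(NULL, ds, train_config(epochs = 6, seed = 1))
  h <- tidy(net)
  expect_identical(nrow(h), 6L) # history length equals epochs
  expect_true(all(diff(h$train_loss) < 0)) # monotone decrease
  expect_lt(h$train_loss[6], 0.75 * h$train_loss[1])
})

test_that("training metadata echoes the published batch size and epoch count", {
  tc <- train_config()
  expect_identical(tc$batch_size, 128L)
  expect_identical(tc$epochs, 10L)
  expect_equal(tc$learning_rate, 0.001)
  expect_equal(c(tc$beta1, tc$beta2, tc$epsilon), c(0.9, 0.999, 1e-07))

  ds <- generate_dataset(90, test_config(), seed = 12, recording_duration = 3)
  net <- train_denoiser(NULL, ds, train_config(epochs = 2, seed = 4))
  expect_identical(net$train_config$batch_size, 128L)
  expect_identical(glance(net)$epochs, 2L)
  expect_identical(glance(net)$seed, 4)
  expect_error(train_denoiser(NULL, generate_dataset(0, test_config()), train_config()),
               class = "blinkclean_value_error")
})

test_that("training is deterministic under a fixed seed", {
  ds <- generate_dataset(120, test_config(), seed = 13, recording_duration = 4)
  n1 <- train_denoiser(NULL, ds, train_config(epochs = 2, seed = 99))
  n2 <- train_denoiser(NULL, ds, train_config(epochs = 2, seed = 99))
  expect_identical(n1$history, n2$history)
  expect_identical(n1$weights, n2$weights)
})

test_that("cleaning a recording conserves shape and passes the reference through", {
  ds <- generate_dataset(120, test_config(), seed = 14, recording_duration = 4)
  net <- train_denoiser(NULL, ds, train_config(epochs = 1, seed = 5))
  pair <- generate_recording(3, test_config(), seed = 15)
  cleaned <- clean_recording(net, pair$contaminated)
  expect_equal(dim(cleaned$data), dim(pair$contaminated$data))
  expect_identical(cleaned$channel_names, pair$contaminated$channel_names)
  expect_equal(cleaned$sampling_rate, pair$contaminated$sampling_rate)
  expect_identical(cleaned$data["Fp1", ], pair$contaminated$data["Fp1", ])

  # a trailing partial window is zero-padded and truncated back
  short <- eeg_recording(pair$contaminated$data[, 1:1000], 512,
                         pair$contaminated$channel_names)
  out <- clean_recording(net, short)
  expect_equal(ncol(out$data), 1000L)

  wrong_rate <- eeg_recording(pair$contaminated$data, 256, pair$contaminated$channel_names)
  expect_error(clean_recording(net, wrong_rate), class = "blinkclean_value_error")
  expect_error(clean_recording(net, pair$contaminated, "nope"), class = "blinkclean_key_error")
})

test_that("models round-trip through disk bit-exactly", {
  ds <- generate_dataset(60, test_config(), seed = 16, recording_duration = 2)
  net <- train_denoiser(NULL, ds, train_config(epochs = 1, seed = 6))
  probe_ref <- matrix(rnorm(512), 1)
  probe_con <- matrix(rnorm(512), 1)
  before <- predict_windows(net, probe_ref, probe_con)

  path <- withr::local_tempfile(fileext = ".rds")
  save_denoiser(net, path)
  restored <- load_denoiser(path)
  expect_identical(predict_windows(restored, probe_ref, probe_con), before)
  expect_identical(restored$train_config, net$train_config) # metadata survives
  expect_identical(restored$seed, net$seed)
  expect_true(file.exists(paste0(path, ".json")))

  expect_error(load_denoiser(path, expected_spec = model_spec(256)),
               class = "blinkclean_format_error")
  garbage <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(not = "a model"), garbage)
  expect_error(load_denoiser(garbage), class = "blinkclean_format_error")
})
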