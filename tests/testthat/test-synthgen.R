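test_that("reference spectra are plain DFTs with validated input", {
  # zero window -> zero coefficients
  sp <- derive_reference_spectrum(numeric(512), 512)
  expect_equal(max(Mod(sp$coefficients)), 0)

  # pure 10 Hz sine: energy concentrated in the +/-10 Hz bins, checked against
  # a direct DFT summation oracle at those bins
  t_s <- (0:511) / 512
  x <- sin(2 * pi * 10 * t_s)
  sp <- derive_reference_spectrum(x, 512)
  dft_bin <- function(x, k) {
    n <- length(x)
    sum(x * exp(-2i * pi * k * (seq_len(n) - 1) / n))
  }
  expect_equal(sp$coefficients[11], dft_bin(x, 10), tolerance = 1e-10) # bin k=10 is 10 Hz
  mags <- Mod(sp$coefficients)
  expect_gt(sum(mags[c(11, 503)]^2) / sum(mags^2), 0.999)

  # a 1-s window at 512 Hz spans exactly 512 samples
  cfg <- test_config()
  expect_identical(cfg$window_samples, 512L)
  expect_error(generator_config(window_samples = 400), class = "blinkclean_value_error")

  expect_error(derive_reference_spectrum(c(1, NA, 3), 512), class = "blinkclean_value_error")
  expect_error(derive_reference_spectrum(numeric(1), 512), class = "blinkclean_size_error")
})

test_that("pink reference windows are 1/f noise inside the amplitude ranges", {
  cfg <- test_config()
  w1 <- pink_reference(cfg, seed = 7)
  w2 <- pink_reference(cfg, seed = 7)
  expect_identical(w1, w2) # bit-identical under a fixed seed
  expect_length(w1, 512)

  # averaged log-spectrum over 200 windows has negative slope vs log-frequency
  # (least-squares slope on the averaged periodogram)
  w <- generate_clean_windows(200, cfg, seed = 8)
  amp <- rowMeans(vapply(seq_len(200), function(i) {
    amplitude_spectrum(w[, i], 512)$amplitude
  }, numeric(257)))
  f <- amplitude_spectrum(w[, 1], 512)$frequency
  keep <- 2:250
  slope <- stats::coef(stats::lm(log(amp[keep]) ~ log(f[keep])))[[2]]
  expect_lt(slope, -0.3)

  sds <- vapply(1:50, function(i) sd(pink_reference(cfg, seed = i)), numeric(1))
  expect_true(all(sds >= cfg$std_range[1] & sds <= cfg$std_range[2]))
})

test_that("spectrum perturbation is bounded, Hermitian, and an identity at zero jitter", {
  cfg <- test_config()
  ref <- pink_reference(cfg, seed = 3)
  sp <- derive_reference_spectrum(ref, 512)

  cfg0 <- generator_config(spectrum_jitter = 0)
  w0 <- generate_clean_window(sp, cfg0, seed = 1)
  expect_equal(as.numeric(w0), ref, tolerance = 1e-12) # zero jitter reproduces the reference

  w <- generate_clean_window(sp, cfg, seed = 2)
  expect_lte(attr(w, "max_perturbation"), cfg$spectrum_jitter)
  expect_true(is.double(w) && !is.complex(w))

  # the mirrored coefficient array must annihilate the imaginary part; a
  # deliberately broken (non-Hermitian) spectrum is rejected
  bad <- sp$coefficients
  bad[2] <- bad[2] + 5
  expect_error(blinkclean:::ifft_real(cbind(bad)), class = "blinkclean_value_error")

  short <- derive_reference_spectrum(numeric(256) + rnorm(256), 512)
  expect_error(generate_clean_window(short, cfg), class = "blinkclean_size_error")
})

test_that("stitching preserves content and bounds every junction jump", {
  cfg <- test_config()
  w <- generate_clean_windows(64, cfg, seed = 21)
  single <- stitch_windows(w[, 1, drop = FALSE], cfg)
  expect_identical(single, drop(w[, 1]))

  x <- stitch_windows(w, cfg)
  expect_length(x, 64 * 512) # length bookkeeping
  junctions <- seq(512, length(x) - 1, by = 512)
  expect_lte(max(abs(x[junctions + 1] - x[junctions])), cfg$stitch_limit)

  expect_error(stitch_windows(list(), cfg), class = "blinkclean_value_error")
})

test_that("blink templates are symmetric Gaussian pulses peaking at the amplitude", {
  expect_equal(max(abs(blink_waveform(0, 0.3, 512))), 0)

  b <- blink_waveform(237.5, 0.3, 512)
  expect_equal(max(b), 237.5)
  peak <- which.max(b)
  expect_equal(b[peak:1], b[peak:length(b)]) # symmetric about the peak

  # direct evaluation of the Gaussian-window formula
  L <- length(b)
  sigma <- (L - 1) / 6
  oracle <- 237.5 * exp(-0.5 * ((0:(L - 1) - (L - 1) / 2) / sigma)^2)
  expect_equal(b, oracle, tolerance = 1e-12)

  expect_error(blink_waveform(10, 0, 512), class = "blinkclean_value_error")
  expect_error(blink_waveform(-1, 0.3, 512), class = "blinkclean_value_error")
})

test_that("blink trains respect the configured interval and amplitude ranges", {
  cfg <- test_config()
  expect_identical(nrow(sample_blink_train(0, cfg, seed = 1)), 0L)

  tr <- sample_blink_train(120, cfg, seed = 2)
  expect_true(all(diff(tr$onset) >= cfg$blink_interval_range[1] - 1e-12))
  expect_true(all(diff(tr$onset) <= cfg$blink_interval_range[2] + 1e-12))
  expect_true(all(tr$amplitude >= 0 & tr$amplitude <= cfg$blink_amp_range[2]))
  expect_true(all(tr$onset < 120))

  # Monte-Carlo oracle: mean event count over seeded 60-s draws is close to
  # duration / mean-gap (uniform gaps on [0.5, 4] -> mean 2.25 s)
  counts <- vapply(1:300, function(s) nrow(sample_blink_train(60, cfg, seed = s)), numeric(1))
  expected <- 60 / mean(cfg$blink_interval_range)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.5)
})

test_that("blink propagation is an exact per-channel scaling", {
  b <- blink_signal(sample_blink_train(2, test_config(), seed = 3), 2, 512)
  gains <- c(Fp1 = 1, Cz = 0.4, Oz = 0)
  M <- propagate_blinks(b, gains)
  expect_equal(dim(M), c(3L, length(b)))
  expect_equal(M["Oz", ], rep(0, length(b)))   # zero gain -> zero row
  expect_identical(M["Fp1", ], b)              # unit gain -> identity
  # elementwise linearity
  b2 <- rev(b)
  expect_equal(propagate_blinks(b, gains) + propagate_blinks(b2, gains),
               propagate_blinks(b + b2, gains), tolerance = 1e-12)
  expect_error(propagate_blinks(b, numeric(0)), class = "blinkclean_size_error")
})

test_that("generated recordings are additively contaminated with Fp1 strongest", {
  cfg <- test_config()
  pair <- generate_recording(5, cfg, seed = 31)
  expect_equal(pair$contaminated$data - pair$clean$data, pair$artifact, tolerance = 1e-12)

  # the reference row carries the largest-magnitude artifact
  row_peak <- apply(abs(pair$artifact), 1, max)
  expect_identical(names(which.max(row_peak)), "Fp1")
  expect_equal(pair$gains[["Fp1"]], 1.0)
  expect_true(all(abs(pair$gains[setdiff(cfg$channel_names, "Fp1")]) < 1))

  pair2 <- generate_recording(5, cfg, seed = 31)
  expect_identical(pair$contaminated$data, pair2$contaminated$data) # seeded determinism
  expect_identical(pair$blinks$onset, pair2$blinks$onset)

  expect_error(generate_recording(2.5, cfg), class = "blinkclean_value_error")
})

test_that("paired-window datasets keep exact generator bookkeeping and split", {
  cfg <- test_config()
  empty <- generate_dataset(0, cfg)
  expect_identical(n_examples(empty), 0L)

  ds <- generate_dataset(90, cfg, seed = 41, recording_duration = 3)
  expect_identical(n_examples(ds), 90L)
  expect_identical(sum(ds$metadata$split == "train"), 72L)
  expect_identical(sum(ds$metadata$split == "validation"), 18L)
  expect_true(all(ds$metadata$channel != cfg$reference_channel))

  # every example satisfies contaminated - clean = gain x blink trace, where
  # the blink trace is recoverable from the reference pair (gain 1)
  for (i in seq_len(n_examples(ds))) {
    lhs <- ds$contaminated[i, ] - ds$target[i, ]
    rhs <- ds$metadata$gain[i] * (ds$ref[i, ] - ds$ref_clean[i, ])
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("generator draws satisfy all published bounds over many seeded draws", {
  cfg <- test_config()
  w <- generate_clean_windows(400, cfg, seed = 51)
  expect_lte(max(attr(w, "max_perturbation")), cfg$spectrum_jitter)
  sds <- apply(w, 2, sd)
  p2p <- apply(w, 2, function(x) max(x) - min(x))
  expect_true(all(sds >= cfg$std_range[1] & sds <= cfg$std_range[2]))
  expect_true(all(p2p >= cfg$p2p_range[1] & p2p <= cfg$p2p_range[2]))
  expect_true(all(is.finite(w)))
})
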