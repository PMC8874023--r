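# shared fixtures, built in code

# a montage-complete config used throughout the tests
test_config <- function(...) generator_config(...)

# a small three-source instantaneous mixture with one blink source, for ICA
# recovery checks: sources are (blink train, uniform noise, bimodal noise)
make_blink_mixture <- function(n = 4096, seed = 11) {
  withr::with_seed(seed, {
    cfg <- generator_config()
    train <- sample_blink_train(n / cfg$sampling_rate, cfg)
    blink <- blink_signal(train, n / cfg$sampling_rate, cfg$sampling_rate)
    s2 <- runif(n, -10, 10)
    s3 <- 5 * sign(rnorm(n)) + rnorm(n)
    S <- rbind(blink, s2, s3)
    A <- matrix(c(1.0, 0.5, 0.3,
                  0.4, 1.0, 0.2,
                  0.2, 0.3, 1.0), 3, 3, byrow = TRUE)
    X <- A %*% S
    list(recording = eeg_recording(X, cfg$sampling_rate, c("a", "b", "c")),
         sources = S, mixing = A, blink = blink)
  })
}

# Desk-scale trained denoisers shared by the acceptance checks, trained once
# per session and cached: a 10,000-window / 5-epoch model (seed 20220211) for
# the scaled-down headline comparison, and the same model resumed for 10
# further epochs as the reference model for the ordering-pattern checks.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_dataset <- function() {
  if (is.null(.acceptance_cache$dataset)) {
    .acceptance_cache$dataset <- generate_dataset(10000, generator_config(), seed = 20220211)
  }
  .acceptance_cache$dataset
}

acceptance_model <- function() {
  if (is.null(.acceptance_cache$model)) {
    .acceptance_cache$model <-
      train_denoiser(NULL, acceptance_dataset(), train_config(epochs = 5, seed = 20220211))
  }
  .acceptance_cache$model
}

acceptance_model_extended <- function() {
  if (is.null(.acceptance_cache$model_ext)) {
    .acceptance_cache$model_ext <-
      train_denoiser(acceptance_model(), acceptance_dataset(),
                     train_config(epochs = 10, seed = 20220212))
    .acceptance_cache$dataset <- NULL # free ~160 MB once training is done
  }
  .acceptance_cache$model_ext
}

# held-out synthetic test recordings for the method comparison
acceptance_recording <- function(seed, duration = 60) {
  generate_recording(duration, generator_config(), seed = seed)
}
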