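Package: blinkclean
Title: Eye-Blink Artifact Removal from EEG with a Convolutional Denoiser
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing eye-blink (electrooculographic) artifacts from
    multichannel electroencephalography (EEG) recordings. Provides a synthetic
    EEG/EOG generator that builds surrogate recordings by perturbing reference
    spectra and propagating Gaussian-shaped blink templates across a 16-channel
    10-20 montage; a two-channel one-dimensional convolutional denoising network
    trained with ADAM on paired clean/contaminated windows; reference-channel
    regression and independent component analysis (ICA) baselines; and an
    evaluation suite computing Pearson correlations, MAPE, RMSE, and skewness
    per channel and method. Recordings can be read and written as delimited
    text or European Data Format (EDF), and paired window datasets as columnar
    parquet containers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
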