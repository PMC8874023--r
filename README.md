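# blinkclean

Eye blinks are the dominant physiological artifact in scalp EEG: each blink
injects a roughly Gaussian-shaped transient of up to several hundred
microvolts that is strongest at the fronto-polar electrodes and propagates,
attenuated, across the whole 10–20 montage. blinkclean is an R toolkit for
removing these artifacts from multichannel recordings and for benchmarking
removal methods against each other. It is aimed at EEG researchers who need
artifact-cleaned signals (e.g. before ERP analysis) and at methodologists who
want a controlled synthetic testbed where the ground-truth clean signal is
known.

The package provides:

* **A surrogate EEG/EOG generator.** Clean 1-s windows (512 samples at
  512 Hz) are synthesized by perturbing the Fourier spectrum of a 1/f-noise
  reference window with bounded random coefficients (±2 µV) and inverse
  transforming, enforcing realistic per-window statistics (standard
  deviation 5–15 µV, peak-to-peak 45–100 µV); windows are stitched with
  boundary jumps ≤ 7 µV. Gaussian-window blink templates (amplitude
  0–650 µV, inter-blink gap 0.5–4 s) are propagated across the 16-channel
  montage with a frontal→occipital gain topography, and clean/contaminated
  recording pairs are returned together with the exact artifact matrix.
* **A convolutional denoiser.** The two-channel 1-D network — conv(20×40,
  stride 2, ReLU) → conv(10×20, stride 1, ReLU) → flatten → dense 512 —
  maps synchronous (Fp1 reference, contaminated channel) windows to clean
  windows. Training uses ADAM (lr 0.001, β₁ 0.9, β₂ 0.999, ε 1e-07),
  mean-squared-error loss, minibatches of 128, and an 80/20
  train/validation split; the implementation is pure R on BLAS matrix
  products with gradients verified against finite differences.
* **Two reference methods.** Reference-channel regression
  (`EEG_clear = EEG_noised − B·EOG_ref` with the least-squares propagation
  factor `B = cov⁻¹·(EOG_ref·EEG_noisedᵀ)`), and ICA component rejection
  (zero-phase order-6 Butterworth 1 Hz high-pass, FastICA with 15
  components, automatic removal of the 2 components most correlated with
  the reference).
* **An evaluation suite** computing, per channel and method over 1-s
  windows: Pearson correlation with the clean signal (`c_kk`) and with the
  reference (`c_fp1`), `MAPE = mean(|y−ŷ|/|y|)` (a raw ratio), `RMSE` (µV),
  and moment skewness — plus cross-channel means and descriptive statistics.
* **I/O and a CLI**: recordings as delimited text or EDF (16-bit), paired
  window datasets as parquet containers with JSON sidecars, and an
  `inst/cli/blinkclean.R` script with `generate`, `train`, `clean`,
  `evaluate`, and `benchmark` subcommands.

## Worked example

Generate a paired 10-s recording, clean it by regression, and score the
result:

```r
library(blinkclean)

cfg  <- generator_config()
pair <- generate_recording(10, cfg, seed = 42)
pair$contaminated
#> <eeg_recording> 16 channels x 5120 samples @ 512 Hz (10.00 s)
#> channels: Fp1, F9, F7, F3, Fz, F4, F8, C3, Cz, C4, P3, Pz, P4, O1, O2, Oz

fit <- regression_clean(pair$contaminated, "Fp1")
glance(fit)
#> # A tibble: 1 × 5
#>   reference_channel       cov n_channels n_samples max_abs_B
#>   <chr>                 <dbl>      <int>     <int>     <dbl>
#> 1 Fp1               47030184.         15      5120     0.758

head(tidy(fit), 4)
#> # A tibble: 4 × 2
#>   channel     B
#>   <chr>   <dbl>
#> 1 F9      0.727
#> 2 F7      0.657
#> 3 F3      0.652
#> 4 Fz      0.618

rep <- compare_methods(pair$clean, pair$contaminated,
                       list(reg = fit$cleaned, none = pair$contaminated))
glance(rep)
#> # A tibble: 2 × 7
#>   method  c_kk  c_fp1  mape  rmse skewness n_channels
#>   <chr>  <dbl>  <dbl> <dbl> <dbl>    <dbl>      <int>
#> 1 none   0.674  0.468 10.1   29.3   0.909          16
#> 2 reg    0.890 -0.101  8.82  15.9   0.0845         16
```

The recovered propagation factors `B` track the gain topography the blinks
were injected with (frontal channels near 0.65–0.73, decaying occipitally).
Doing nothing (`none`) leaves a mean error ratio (MAPE) of 10.1, a strong
correlation with the blink reference (0.468), and a blink-skewed amplitude
distribution; regression removes the reference correlation (−0.101, by
construction near zero over the whole recording), halves the RMSE, and
brings skewness near zero. Training the network and adding it to the
comparison works the same way via `generate_dataset()`, `train_denoiser()`,
and `clean_recording()` — see the methods vignette for the model sizes and
what each method's residual error is made of.

`autoplot()` methods exist for recordings, metric reports, fitted regression
objects, and training histories; `run_pipeline(pipeline_config(...))`
orchestrates generate → train → clean → evaluate with resumable on-disk
artifacts.

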