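#' Configuration for the end-to-end pipeline
#'
#' A flat key-value configuration covering generation, training, cleaning, and
#' evaluation. Unknown keys are rejected; the whole configuration is echoed
#' into every artifact's JSON sidecar.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param n_windows Training examples to generate (default 10000).
#' @param test_duration Held-out test recording length in seconds (default 60).
#' @param epochs,batch_size Training parameters (defaults 10 / 128).
#' @param n_components,n_remove,highpass_cutoff,filter_order ICA parameters.
#' @param seed Master seed; stage seeds are derived from it.
#' @param verbose Emit per-stage log messages (default TRUE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, n_windows = 10000, test_duration = 60,
                            epochs = 10, batch_size = 128,
                            n_components = 15, n_remove = 2,
                            highpass_cutoff = 1, filter_order = 6,
                            seed = 20220211, verbose = TRUE) {
  args <- as.list(environment())
  structure(args, class = "pipeline_config")
}

pipeline_log <- function(config, stage, fmt, ...) {
  if (isTRUE(config$verbose)) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
}

#' Run the full generate / train / clean / evaluate pipeline
#'
#' Orchestrates the four stages, writing resumable artifacts under
#' `config$out_dir`: `dataset.parquet`, `test_pair.rds`, `model.rds`,
#' `cleaned_<method>.csv`, and `report_per_channel.csv` /
#' `report_summary.csv`. A stage whose artifact already exists is skipped, so
#' deleting an intermediate re-runs only the downstream stages. Every artifact
#' carries a JSON sidecar with the configuration echo and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `report` (the `metric_report`), `paths`
#'   (artifact locations), and `status` (0 on success).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) value_error("`config` must be a pipeline_config().")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    dataset = file.path(config$out_dir, "dataset.parquet"),
    test_pair = file.path(config$out_dir, "test_pair.rds"),
    model = file.path(config$out_dir, "model.rds"),
    report_per_channel = file.path(config$out_dir, "report_per_channel.csv"),
    report_summary = file.path(config$out_dir, "report_summary.csv")
  )
  gen_cfg <- generator_config(seed = config$seed)
  stage <- function(name, artifact, produce) {
    if (all(file.exists(artifact))) {
      pipeline_log(config, name, "artifact up to date: %s", paste(artifact, collapse = ", "))
      return(invisible(FALSE))
    }
    tryCatch(produce(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "blinkclean_pipeline_error", parent = e)
    })
    invisible(TRUE)
  }

  stage("generate", c(paths$dataset, paths$test_pair), function() {
    pipeline_log(config, "generate", "n_windows=%d test_duration=%ds seed=%d",
                 config$n_windows, config$test_duration, config$seed)
    ds <- generate_dataset(config$n_windows, gen_cfg, seed = config$seed)
    write_dataset(ds, paths$dataset)
    pair <- generate_recording(config$test_duration, gen_cfg, seed = config$seed + 1000L)
    saveRDS(pair, paths$test_pair)
  })

  stage("train", paths$model, function() {
    pipeline_log(config, "train", "epochs=%d batch_size=%d seed=%d",
                 config$epochs, config$batch_size, config$seed)
    ds <- read_dataset(paths$dataset)
    tc <- train_config(epochs = config$epochs, batch_size = config$batch_size,
                       seed = config$seed)
    model <- train_denoiser(NULL, ds, tc)
    save_denoiser(model, paths$model)
  })

  methods <- c("cnn", "reg", "ica")
  cleaned_paths <- setNames(file.path(config$out_dir, sprintf("cleaned_%s.csv", methods)), methods)
  paths$cleaned <- cleaned_paths
  stage("clean", cleaned_paths, function() {
    pair <- readRDS(paths$test_pair)
    model <- load_denoiser(paths$model)
    icfg <- ica_config(n_components = config$n_components, n_remove = config$n_remove,
                       highpass_cutoff = config$highpass_cutoff,
                       filter_order = config$filter_order, seed = config$seed)
    outs <- list(
      cnn = clean_recording(model, pair$contaminated),
      reg = regression_clean(pair$contaminated)$cleaned,
      ica = ica_clean(pair$contaminated, config = icfg)$cleaned
    )
    for (m in methods) {
      pipeline_log(config, "clean", "method=%s", m)
      write_recording(outs[[m]], cleaned_paths[[m]],
                      metadata = list(method = m, config = unclass(config)))
    }
  })

  stage("evaluate", c(paths$report_per_channel, paths$report_summary), function() {
    pipeline_log(config, "evaluate", "writing %s", paths$report_per_channel)
    pair <- readRDS(paths$test_pair)
    icfg <- ica_config(n_components = config$n_components, n_remove = config$n_remove,
                       highpass_cutoff = config$highpass_cutoff,
                       filter_order = config$filter_order, seed = config$seed)
    cleaned <- list(
      cnn = read_recording(cleaned_paths[["cnn"]]),
      reg = read_recording(cleaned_paths[["reg"]]),
      ica = list(cleaned = read_recording(cleaned_paths[["ica"]]),
                 clean = highpass_filter(pair$clean, icfg$highpass_cutoff, icfg$filter_order))
    )
    report <- compare_methods(pair$clean, pair$contaminated, cleaned)
    readr::write_csv(report$per_channel, paths$report_per_channel)
    readr::write_csv(report$summary, paths$report_summary)
  })

  report <- list(
    per_channel = readr::read_csv(paths$report_per_channel, show_col_types = FALSE),
    summary = readr::read_csv(paths$report_summary, show_col_types = FALSE)
  )
  invisible(list(status = 0L, report = report, paths = paths))
}
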