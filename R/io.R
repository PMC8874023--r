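recording_sidecar_path <- function(path) paste0(path, ".json")

strip_class <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_class) else x
}

#' Write a recording to disk
#'
#' Delimited text (`.csv`, `.tsv`, `.txt`: header row of channel names, first
#' column `time` in seconds) or EDF (`.edf`: 16-bit, physical range set from
#' the data). A JSON metadata sidecar (`<path>.json`) echoes the sampling
#' rate, channel order, and any supplied metadata such as the generation seed.
#'
#' @param recording An [eeg_recording()].
#' @param path Destination file; the extension selects the format.
#' @param metadata Optional named list merged into the sidecar (e.g.
#'   `list(seed = 1)`).
#' @return `path`, invisibly.
#' @examples
#' pair <- generate_recording(1, generator_config(), seed = 1)
#' p <- file.path(tempdir(), "rec.csv")
#' write_recording(pair$clean, p, metadata = list(seed = 1))
#' rec <- read_recording(p)
#' @export
write_recording <- function(recording, path, metadata = list()) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv", "txt")) {
    df <- tibble(time = (seq_len(n_samples(recording)) - 1L) / recording$sampling_rate)
    for (ch in recording$channel_names) df[[ch]] <- recording$data[ch, ]
    delim <- if (ext == "csv") "," else "\t"
    readr::write_delim(df, path, delim = delim)
  } else if (ext == "edf") {
    write_edf(recording, path)
  } else {
    format_error(sprintf("unsupported recording format '.%s' (use csv, tsv, txt, or edf).", ext))
  }
  sidecar <- c(
    list(sampling_rate = recording$sampling_rate,
         channel_names = recording$channel_names,
         n_samples = n_samples(recording), format = ext),
    strip_class(metadata)
  )
  jsonlite::write_json(sidecar, recording_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path A `.csv`/`.tsv`/`.txt` file (header row of channel names,
#'   optional leading `time` column) or an `.edf` file.
#' @param sampling_rate Sampling rate in Hz for delimited files without a time
#'   column; ignored when a time column or EDF header provides it.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) value_error(sprintf("'%s' does not exist.", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(read_edf(path))
  if (!ext %in% c("csv", "tsv", "txt")) {
    format_error(sprintf("unsupported recording format '.%s' (use csv, tsv, txt, or edf).", ext))
  }
  delim <- if (ext == "csv") "," else "\t"
  df <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE),
    error = function(e) format_error(sprintf("could not parse '%s': %s", path, conditionMessage(e)))
  )
  if (ncol(df) == 0L || nrow(df) == 0L) format_error(sprintf("'%s' contains no data.", path))
  if (any(grepl("^[-0-9.eE+]+$", names(df)))) {
    format_error(sprintf("'%s' has no header row of channel names.", path))
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    format_error(sprintf("'%s' has non-numeric or inconsistent rows.", path))
  }
  if (tolower(names(df)[1]) == "time") {
    t_col <- df[[1]]
    df <- df[-1]
    if (nrow(df) > 1) sampling_rate <- 1 / stats::median(diff(t_col))
  }
  if (is.null(sampling_rate)) {
    value_error("no time column found; supply `sampling_rate`.")
  }
  eeg_recording(t(as.matrix(df)), sampling_rate, names(df))
}

#' Write a paired-window dataset as a parquet container
#'
#' The aligned example windows are stored as list columns (`ref`,
#' `contaminated`, `target`, `ref_clean`) next to the metadata columns in a
#' single columnar parquet file, with a JSON sidecar echoing the generator
#' configuration, the seed, and the split sizes.
#'
#' @param dataset A [generate_dataset()] result.
#' @param path Destination `.parquet` file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  n <- n_examples(dataset)
  df <- dataset$metadata
  df$ref <- lapply(seq_len(n), function(i) dataset$ref[i, ])
  df$contaminated <- lapply(seq_len(n), function(i) dataset$contaminated[i, ])
  df$target <- lapply(seq_len(n), function(i) dataset$target[i, ])
  df$ref_clean <- lapply(seq_len(n), function(i) dataset$ref_clean[i, ])
  arrow::write_parquet(df, path)
  jsonlite::write_json(
    list(config = strip_class(dataset$config), seed = dataset$seed,
         n_examples = n,
         n_train = sum(dataset$metadata$split == "train"),
         n_validation = sum(dataset$metadata$split == "validation")),
    recording_sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a paired-window dataset written by [write_dataset()]
#'
#' @param path A `.parquet` file.
#' @return A `paired_window_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) value_error(sprintf("'%s' does not exist.", path))
  df <- as.data.frame(arrow::read_parquet(path))
  needed <- c("ref", "contaminated", "target", "ref_clean")
  if (!all(needed %in% names(df))) format_error(sprintf("'%s' is not a paired-window dataset.", path))
  to_mat <- function(col) do.call(rbind, lapply(df[[col]], as.numeric))
  meta <- as_tibble(df[setdiff(names(df), needed)])
  sidecar_path <- recording_sidecar_path(path)
  cfg <- generator_config()
  seed <- NULL
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    seed <- side$seed
    if (!is.null(side$config)) {
      cfg_fields <- side$config
      cfg <- generator_config(
        sampling_rate = cfg_fields$sampling_rate,
        std_range = cfg_fields$std_range, p2p_range = cfg_fields$p2p_range,
        spectrum_jitter = cfg_fields$spectrum_jitter, stitch_limit = cfg_fields$stitch_limit,
        blink_amp_range = cfg_fields$blink_amp_range,
        blink_interval_range = cfg_fields$blink_interval_range,
        blink_width_range = cfg_fields$blink_width_range,
        channel_names = cfg_fields$channel_names,
        propagation_gains = unlist(cfg_fields$propagation_gains),
        gain_jitter = cfg_fields$gain_jitter,
        reference_channel = cfg_fields$reference_channel,
        seed = cfg_fields$seed
      )
    }
  }
  structure(
    list(ref = to_mat("ref"), contaminated = to_mat("contaminated"),
         target = to_mat("target"), ref_clean = to_mat("ref_clean"),
         metadata = meta, config = cfg, seed = seed),
    class = "paired_window_dataset"
  )
}
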