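# Minimal European Data Format (EDF) writer/reader: 16-bit samples, physical
# range taken from the data, one 1-s data record per second when the length
# allows, otherwise a single record spanning the recording.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width) # left-justified, space padded
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = width), 1, width)
  edf_pad(s, width)
}

#' Write a recording as an EDF file
#'
#' Samples are quantized to 16 bits over each channel's physical range, so the
#' per-sample round-trip error is bounded by `range / 2^16`.
#'
#' @param recording An [eeg_recording()].
#' @param path Destination `.edf` file.
#' @return `path`, invisibly.
#' @keywords internal
write_edf <- function(recording, path) {
  data <- recording$data
  fs <- recording$sampling_rate
  ns <- ncol(data)
  n_sig <- nrow(data)
  if (ns %% fs == 0 && fs == round(fs)) {
    n_rec <- ns %/% fs
    rec_dur <- 1
    spr <- as.integer(fs)
  } else {
    n_rec <- 1L
    rec_dur <- ns / fs
    spr <- as.integer(ns)
  }
  pmin_v <- apply(data, 1, min)
  pmax_v <- apply(data, 1, max)
  flat <- pmax_v - pmin_v < 1e-9
  pmax_v[flat] <- pmin_v[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (n_sig + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_num(rec_dur, 8), edf_pad(n_sig, 4),
    paste(vapply(recording$channel_names, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), n_sig), collapse = ""),
    paste(rep(edf_pad("uV", 8), n_sig), collapse = ""),
    paste(vapply(pmin_v, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax_v, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(-32768, 8), n_sig), collapse = ""),
    paste(rep(edf_pad(32767, 8), n_sig), collapse = ""),
    paste(rep(edf_pad("", 80), n_sig), collapse = ""),
    paste(rep(edf_pad(spr, 8), n_sig), collapse = ""),
    paste(rep(edf_pad("", 32), n_sig), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (pmax_v - pmin_v) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(n_sig)) {
      dig <- round((data[s, idx] - pmin_v[s]) / scale[s]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_field <- function(con, width, n = 1L) {
  vapply(seq_len(n), function(i) trimws(readChar(con, width, useBytes = TRUE)), "")
}

#' Read an EDF file into a recording
#'
#' @param path An `.edf` file written by [write_recording()] (or any EDF with
#'   a uniform sampling rate).
#' @return An [eeg_recording()].
#' @keywords internal
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_field(con, 8)
  if (!identical(version, "0")) format_error(sprintf("'%s' is not an EDF file.", path))
  invisible(read_edf_field(con, 80, 2)) # patient / recording id
  invisible(read_edf_field(con, 8, 2))  # date / time
  invisible(read_edf_field(con, 8))     # header bytes
  invisible(read_edf_field(con, 44))
  n_rec <- as.integer(read_edf_field(con, 8))
  rec_dur <- as.numeric(read_edf_field(con, 8))
  n_sig <- as.integer(read_edf_field(con, 4))
  if (is.na(n_sig) || n_sig < 1) format_error("corrupt EDF header (signal count).")
  labels <- read_edf_field(con, 16, n_sig)
  invisible(read_edf_field(con, 80, n_sig))
  invisible(read_edf_field(con, 8, n_sig)) # dimension
  pmin_v <- as.numeric(read_edf_field(con, 8, n_sig))
  pmax_v <- as.numeric(read_edf_field(con, 8, n_sig))
  dmin <- as.numeric(read_edf_field(con, 8, n_sig))
  dmax <- as.numeric(read_edf_field(con, 8, n_sig))
  invisible(read_edf_field(con, 80, n_sig))
  spr <- as.integer(read_edf_field(con, 8, n_sig))
  invisible(read_edf_field(con, 32, n_sig))
  if (length(unique(spr)) != 1L) format_error("EDF files with mixed rates are not supported.")
  data <- matrix(0, n_sig, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (s in seq_len(n_sig)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little", signed = TRUE)
      if (length(dig) < spr[1]) format_error("EDF data payload is truncated.")
      data[s, idx] <- (dig - dmin[s]) / (dmax[s] - dmin[s]) * (pmax_v[s] - pmin_v[s]) + pmin_v[s]
    }
  }
  eeg_recording(data, spr[1] / rec_dur, labels)
}
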