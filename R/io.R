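#' Write a condition's rasters as tidy CSV
#'
#' Long format with header `neuron_id, token_id, level_db, snr_db, trial,
#' bin_index, spike`; only spike = 1 rows are stored (zeros are implicit given
#' the known geometry), which keeps files tractable at 1-ms binning.
#'
#' @param cr a `condition_response`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_raster_csv <- function(cr, path) {
  stopifnot(inherits(cr, "condition_response"))
  sm <- Matrix::summary(cr$m)
  B <- cr$n_bins
  df <- data.frame(
    neuron_id = cr$neuron_id[(sm$j - 1) %/% B + 1],
    token_id = cr$rows$token_id[sm$i],
    level_db = cr$level_db, snr_db = cr$snr_db,
    trial = cr$rows$trial[sm$i],
    bin_index = (sm$j - 1) %% B + 1,
    spike = 1L
  )
  df <- df[order(df$token_id, df$trial, df$neuron_id, df$bin_index), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read rasters written by [write_raster_csv()]
#'
#' @param path CSV path.
#' @param neuron_ids full neuron id vector (needed to restore silent neurons).
#' @param n_bins bins per neuron.
#' @param n_trials trials per token.
#' @param token_ids full token id vector (restores tokens with no spikes).
#' @param arm arm label to stamp on the result.
#' @return a `condition_response`.
#' @export
read_raster_csv <- function(path, neuron_ids, n_bins, n_trials,
                            token_ids = NULL, arm = "control") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(token_ids)) token_ids <- sort(unique(df$token_id))
  rows <- tibble(
    token_id = rep(token_ids, each = n_trials),
    trial = rep(seq_len(n_trials), length(token_ids))
  )
  ri <- match(paste(df$token_id, df$trial), paste(rows$token_id, rows$trial))
  ci <- (match(df$neuron_id, neuron_ids) - 1) * n_bins + df$bin_index
  structure(list(
    m = sparseMatrix(i = ri, j = ci, x = 1,
                     dims = c(nrow(rows), length(neuron_ids) * n_bins)),
    rows = rows, neuron_id = neuron_ids, n_bins = n_bins, n_trials = n_trials,
    arm = arm, level_db = df$level_db[1], snr_db = df$snr_db[1]
  ), class = "condition_response")
}

#' Write a neurogram as dense CSV with a CF sidecar
#'
#' @param ng a `neurogram`.
#' @param path CSV path for the matrix; the sidecar of row CFs is written to
#'   `<path>` with suffix `_cf.csv`.
#' @return invisibly, the two paths.
#' @export
write_neurogram_csv <- function(ng, path) {
  stopifnot(inherits(ng, "neurogram"))
  write.csv(as.data.frame(ng$values), path, row.names = FALSE)
  side <- sub("\\.csv$", "_cf.csv", path)
  write.csv(data.frame(neuron_id = ng$neuron_id, cf_hz = ng$cf_order),
            side, row.names = FALSE)
  invisible(c(path, side))
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' A minimal RIFF/WAVE writer (none of the installed packages provides one).
#' Samples are clipped to \[-1, 1\] and scaled to the 16-bit range.
#'
#' @param wave numeric waveform in \[-1, 1\] (calibrated stimuli are well
#'   inside this range).
#' @param path output path.
#' @param fs sample rate in Hz (default: the waveform's `fs` attribute).
#' @return invisibly, `path`.
#' @export
write_wav <- function(wave, path, fs = attr(wave, "fs")) {
  stopifnot(!is.null(fs))
  x <- as.integer(round(pmin(pmax(as.numeric(wave), -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little") # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV written by [write_wav()]
#'
#' @param path WAV path.
#' @return numeric waveform in \[-1, 1\] with attribute `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
    } else if (id == "data") {
      x <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little",
                   signed = TRUE)
      out <- x / 32767
      attr(out, "fs") <- fs
      return(out)
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
}
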