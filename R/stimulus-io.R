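# Stimulus serialization: two-column CSV, and minimal mono 16-bit PCM WAV
# written directly as a RIFF chunk stream (readBin/writeBin); round trips are
# exact to the 1-LSB quantization of the PCM encoding.

#' Write a stimulus to CSV or WAV
#'
#' Voltage sequences (`stimulus_tbl`) serialize as two-column CSV with a
#' `index,value` header; sampled signals serialize either as `time_s,value`
#' CSV or as mono 16-bit PCM WAV at their sample rate.
#'
#' @param x A `stimulus_tbl` or audio/signal tibble from this package.
#' @param path Output file path.
#' @param format `"csv"` or `"wav"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @seealso [read_stimulus()]
#' @export
write_stimulus <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  }
  format <- match.arg(format, c("csv", "wav"))
  if (format == "wav") {
    if (!"time" %in% names(x)) {
      abort("WAV output requires a time-sampled signal, not a stepped sequence.")
    }
    wav_write(x$value, sample_rate(x), path)
  } else {
    if ("step" %in% names(x)) {
      df <- data.frame(index = x$step, value = x$value)
    } else {
      df <- data.frame(time_s = x$time, value = x$value)
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a stimulus written by [write_stimulus()]
#'
#' @param path A `.csv` (`index,value` or `time_s,value`) or `.wav` file.
#' @param sample_rate Sample rate override for index-based CSV files.
#' @return A tibble: `step`/`value` for index CSVs, `time`/`value` (with a
#'   `sample_rate` attribute) for time CSVs and WAV files.
#' @export
read_stimulus <- function(path, sample_rate = NULL) {
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    w <- wav_read(path)
    return(sig_tbl(w$samples, w$sample_rate, class = "audio_tbl"))
  }
  df <- utils::read.csv(path)
  if ("index" %in% names(df)) {
    out <- tibble(step = as.integer(df$index), value = df$value)
    class(out) <- c("stimulus_tbl", class(out))
    out
  } else {
    tm <- df[[1]]
    fs <- if (is.null(sample_rate)) 1 / median(diff(tm)) else sample_rate
    sig_tbl(df$value, fs, t0 = tm[1])
  }
}

wav_write <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") abort("not a RIFF/WAVE file")
  sample_rate <- NA_real_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", sz - 8)
      if (fmt[1] != 1L || fmt[2] != 1L) abort("only mono 16-bit PCM supported")
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", sz)
    }
  }
}
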