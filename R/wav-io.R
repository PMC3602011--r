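#' Read a mono PCM WAV file
#'
#' Reads a 16-bit PCM mono RIFF/WAVE file into a numeric vector scaled to
#' [-1, 1]. Only the subset of the format produced by [write_wav()] (and by
#' typical field recorders: linear PCM, single channel) is supported.
#'
#' @param path Path to a `.wav` file.
#' @return A list with elements `samples` (numeric vector in [-1, 1]) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL
  bits <- NULL
  n_channels <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only linear PCM supported")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little") # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little") # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("data chunk before fmt chunk")
      if (bits != 16L) stop("only 16-bit PCM supported")
      if (n_channels != 1L) stop("only mono supported")
      n <- size %/% 2L
      x <- readBin(con, "integer", n, size = 2, signed = TRUE,
                   endian = "little")
      return(list(samples = x / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", size)
    }
  }
}

#' Write a mono PCM WAV file
#'
#' @param samples Numeric vector in [-1, 1]; values outside are clipped.
#' @param sample_rate Sampling rate in Hz (e.g. 48000).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little") # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read or write selection tables
#'
#' Selection tables are tab-delimited annotation files with one row per
#' syllable: `file, song_id, trill_id, syllable_idx, begin_s, end_s,
#' low_hz, high_hz, trill_type`. Times are seconds from recording start
#' (half-open intervals), frequencies Hz.
#'
#' @param path Path to a tab-delimited selection table.
#' @return A data frame with one row per annotated syllable.
#' @export
read_selection_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("file", "song_id", "trill_id", "syllable_idx",
                "begin_s", "end_s", "low_hz", "high_hz", "trill_type")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("selection table missing columns: ", paste(missing, collapse = ", "))
  tab
}

#' @rdname read_selection_table
#' @param tab Data frame of syllable annotations.
#' @export
write_selection_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
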