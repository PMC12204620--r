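# Minimal mono PCM-16 WAV reader/writer.  No audio package ships with this
# environment, and the format is a fixed RIFF layout, so the two functions
# below implement exactly the subset the pipeline emits: 16-bit signed PCM,
# one channel, arbitrary sample rate.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param waveform numeric vector in \[-1, 1\]; values outside are clipped.
#' @param path output file path.
#' @param sample_rate samples per second (default 44100).
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate = 44100L) {
  if (!is.numeric(waveform) || length(waveform) == 0L)
    stop_fmt("write_wav: empty or non-numeric waveform for '%s'", path)
  pcm <- as.integer(round(pmax(-1, pmin(1, waveform)) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file written by [write_wav()] or any mono PCM-16 file.
#' @return list with `waveform` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_fmt("read_wav: no such file '%s'", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF"))
    stop_fmt("read_wav: '%s' is not a RIFF file", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE"))
    stop_fmt("read_wav: '%s' is not a WAVE file", path)
  sample_rate <- NA_integer_; bits <- NA_integer_; channels <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L)
      stop_fmt("read_wav: no data chunk in '%s'", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      if (channels != 1L || bits != 16L)
        stop_fmt("read_wav: '%s' is not mono PCM-16 (channels=%d, bits=%d)",
                 path, channels, bits)
      pcm <- readBin(con, "integer", size / 2L, size = 2, endian = "little",
                     signed = TRUE)
      return(list(waveform = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", size + size %% 2L)   # skip unknown chunk (padded)
    }
  }
}
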