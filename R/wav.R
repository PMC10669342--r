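# Minimal RIFF/PCM WAV codec: 16-bit signed little-endian, mono or multi-channel
# read, mono write. Covers exactly the containers the corpus generator emits.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantised to signed 16-bit integers.
#'
#' @param samples Numeric vector of samples in \[-1, 1\].
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path Path to a RIFF PCM WAV file (16-bit).
#' @return List with `samples` (numeric in \[-1, 1\], first channel if
#'   multi-channel) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NA_integer_
  n_channels <- 1L
  bits <- 16L
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16L)
    } else if (identical(id, "data")) {
      if (bits != 16L) stop("only 16-bit PCM supported, got ", bits, "-bit")
      pcm <- readBin(con, integer(), n = size %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
      if (n_channels > 1L) pcm <- pcm[seq(1L, length(pcm), by = n_channels)]
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, raw(), n = size + size %% 2L)
    }
  }
}
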