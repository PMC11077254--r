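#' Write a signal as a mono 16-bit PCM WAV file
#'
#' Samples are clipped to the range -1..1 and quantized to 16 bits; the header
#' carries the signal's own sample rate.
#'
#' @param s An `enrichment_signal` (nonempty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(s, path) {
  stopifnot(inherits(s, "enrichment_signal"))
  n <- length(s$samples)
  if (n == 0) rlang::abort("cannot write an empty signal")
  pcm <- as.integer(round(pmin(pmax(s$samples, -1), 1) * 32767))
  data_size <- 2L * n
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(s$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(s$sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path Path to a WAV file written by [write_wav()] (or any plain
#'   mono PCM16 RIFF file).
#' @return An `enrichment_signal` with samples on the range -1..1.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) rlang::abort("not a RIFF/WAV file")
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) rlang::abort("not a WAVE file")
  sample_rate <- NA_integer_
  bits <- NA_integer_
  channels <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      readBin(con, integer(), size = 2, endian = "little") # format tag
      channels <- readBin(con, integer(), size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little") # byte rate
      readBin(con, integer(), size = 2, endian = "little") # block align
      bits <- readBin(con, integer(), size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) readBin(con, raw(), n = extra)
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                         endian = "little")
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(samples)) rlang::abort("no data chunk found")
  if (!identical(channels, 1L) || !identical(bits, 16L)) {
    rlang::abort("only mono 16-bit PCM WAV is supported")
  }
  new_signal(samples / 32767, sample_rate, meta = list(source = path))
}
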