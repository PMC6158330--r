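#' Minimal mono PCM16 WAV reader and writer
#'
#' Reads and writes canonical RIFF/WAVE files with 16-bit integer PCM
#' samples, the format produced by typical lab recording chains. Samples are
#' scaled to [-1, 1]. Only mono PCM16 is supported; anything else raises an
#' error naming the offending header field.
#'
#' @param path File path.
#' @param wave Numeric vector in [-1, 1].
#' @param fs Sampling rate (Hz).
#' @return `read_wav()` returns `list(wave, fs)`; `write_wav()` the path,
#'   invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; n_channels <- NULL; bits <- NULL; audio <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), 2L, size = 2L, endian = "little")
      if (fmt[1] != 1L) stop("unsupported WAV encoding (AudioFormat != PCM)")
      n_channels <- fmt[2]
      fs <- readBin(con, integer(), 1L, size = 4L, endian = "little")
      invisible(readBin(con, integer(), 1L, size = 4L, endian = "little"))
      invisible(readBin(con, integer(), 1L, size = 2L, endian = "little"))
      bits <- readBin(con, integer(), 1L, size = 2L, endian = "little")
      if (size > 16L) invisible(readBin(con, raw(), size - 16L))
    } else if (identical(id, "data")) {
      audio <- readBin(con, integer(), size %/% 2L, size = 2L,
                       endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), size))
    }
  }
  if (is.null(fs) || is.null(audio)) stop("missing fmt or data chunk: ", path)
  if (n_channels != 1L) stop("unsupported WAV: NumChannels must be 1 (mono)")
  if (bits != 16L) stop("unsupported WAV: BitsPerSample must be 16")
  list(wave = audio / 32768, fs = fs)
}

#' @rdname read_wav
#' @export
write_wav <- function(wave, fs, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little") # PCM, mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4L, endian = "little")
  writeBin(c(2L, 16L), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
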