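#' Write a waveform to a RIFF/WAVE file
#'
#' Minimal mono WAV writer supporting 16-bit PCM and IEEE float32 encodings.
#' Writing is deterministic: the same waveform always produces identical
#' bytes.
#'
#' @param wave a `waveform` (see [render_scene()]).
#' @param path output file path.
#' @param encoding `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, encoding = c("pcm16", "float32")) {
  stopifnot(inherits(wave, "waveform"))
  encoding <- match.arg(encoding)
  x <- wave$samples
  fs <- as.integer(wave$rate_hz)
  con <- file(path, "wb")
  on.exit(close(con))
  if (encoding == "pcm16") {
    bits <- 16L; fmt <- 1L
    payload <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  } else {
    bits <- 32L; fmt <- 3L
    payload <- x
  }
  block <- bits %/% 8L
  data_bytes <- length(x) * block
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L); w16(fmt); w16(1L); w32(fs)
  w32(fs * block); w16(block); w16(bits)
  writeChar("data", con, eos = NULL)
  w32(data_bytes)
  if (encoding == "pcm16") writeBin(payload, con, size = 2, endian = "little")
  else writeBin(payload, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' @param path file path.
#' @return a `waveform` (events are not stored in WAV; see the sidecar JSON
#'   written by [write_stimulus_set()]).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", 1, size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", 1, size = 2, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  r32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; fs <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- r32()
    if (id == "fmt ") {
      fmt <- r16(); nch <- r16(); fs <- r32(); r32(); r16(); bits <- r16()
      if (nch != 1L) stop("only mono WAV supported")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      n <- size %/% (bits %/% 8L)
      samples <- if (fmt == 3L)
        readBin(con, "double", n, size = 4, endian = "little")
      else readBin(con, "integer", n, size = 2, endian = "little") / 32767
      break
    } else readBin(con, "raw", size)
  }
  structure(list(samples = samples, rate_hz = fs, events = NULL),
            class = "waveform")
}
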