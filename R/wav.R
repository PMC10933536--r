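# Minimal RIFF/WAVE reader and writer (mono or multi-channel, PCM 16/24-bit
# and IEEE float32). Samples are exchanged as numeric vectors on [-1, 1] full
# scale; only the formats the package itself writes need to be read back.

#' Write a WAV file
#'
#' Writes a single-channel (or multi-channel, columns of a matrix) waveform to
#' a RIFF/WAVE file. Samples are full-scale normalized: +/-1.0 maps to the
#' integer full scale for PCM encodings and is stored as-is for float32.
#'
#' @param samples numeric vector (mono) or matrix (one column per channel)
#' @param fs sampling rate in Hz
#' @param path output file path
#' @param bit_depth one of "float32" (default), "pcm16", "pcm24"
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, fs, path, bit_depth = c("float32", "pcm16", "pcm24")) {
  bit_depth <- match.arg(bit_depth)
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1L)
  n_ch <- ncol(samples)
  n <- nrow(samples)
  interleaved <- as.numeric(t(samples))
  con <- file(path, "wb")
  on.exit(close(con))

  if (bit_depth == "float32") {
    fmt_code <- 3L; bits <- 32L
    data_size <- n * n_ch * 4L
  } else if (bit_depth == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    data_size <- n * n_ch * 2L
  } else {
    fmt_code <- 1L; bits <- 24L
    data_size <- n * n_ch * 3L
  }
  block_align <- n_ch * bits %/% 8L
  byte_rate <- fs * block_align
  fact <- fmt_code == 3L
  riff_size <- 4L + (8L + 16L) + (if (fact) 8L + 4L else 0L) + 8L + data_size

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(riff_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  if (fact) {
    writeChar("fact", con, eos = NULL)
    writeBin(4L, con, size = 4, endian = "little")
    writeBin(as.integer(n), con, size = 4, endian = "little")
  }
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")

  if (bit_depth == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else if (bit_depth == "pcm16") {
    q <- as.integer(pmax(pmin(round(interleaved * 32767), 32767), -32768))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    q <- pmax(pmin(round(interleaved * 8388607), 8388607), -8388608)
    q <- ifelse(q < 0, q + 16777216, q)  # two's complement in 3 bytes
    bytes <- as.raw(rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256))
    writeBin(bytes, con)
  }
  invisible(path)
}

#' Read a WAV file
#'
#' @param path WAV file path
#' @return list with `samples` (numeric vector for mono, matrix otherwise, on
#'   [-1, 1] full scale), `fs` (Hz) and `bit_depth`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") fc_stop(sprintf("not a RIFF file: %s", path), "wav_format")
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") fc_stop(sprintf("not a WAVE file: %s", path), "wav_format")

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, "integer", size = 2, endian = "little"),
        n_ch = readBin(con, "integer", size = 2, endian = "little"),
        fs = readBin(con, "integer", size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", size = 4, endian = "little"),
        block_align = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little"))
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", n = size)
    } else {
      readBin(con, "raw", n = size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    fc_stop(sprintf("missing fmt or data chunk: %s", path), "wav_format")

  if (fmt$code == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", n = length(data_raw) %/% 4L, size = 4,
                 endian = "little")
    bit_depth <- "float32"
  } else if (fmt$code == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L, size = 2,
                 signed = TRUE, endian = "little") / 32767
    bit_depth <- "pcm16"
  } else if (fmt$code == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3L)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388607
    bit_depth <- "pcm24"
  } else {
    fc_stop(sprintf("unsupported WAV encoding (format %d, %d bit)", fmt$code, fmt$bits),
            "wav_format")
  }
  if (fmt$n_ch > 1L) x <- t(matrix(x, nrow = fmt$n_ch))
  list(samples = x, fs = fmt$fs, bit_depth = bit_depth)
}
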