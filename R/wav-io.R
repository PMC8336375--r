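#' Read a RIFF/WAVE file
#'
#' Minimal PCM WAV codec. Supports integer PCM at 16/24/32 bit, 8-bit
#' unsigned PCM, and IEEE float32/64, mono or stereo. Samples are returned
#' as a channels-by-n numeric matrix scaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (matrix, channels x n), `sample_rate`,
#'   `bit_depth`, and `n_channels`.
#' @keywords internal
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("cannot decode audio: file does not exist: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) {
    stop("cannot decode audio (not a RIFF/WAVE file): ", path)
  }
  readBin(con, "integer", 1, 4, endian = "little") # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("cannot decode audio (missing WAVE tag): ", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + (sz %% 2L))
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bit_depth    = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("cannot decode audio (missing fmt/data chunk): ", path)
  }
  if (length(data_raw) == 0L) {
    stop("empty audio: zero-length data chunk in ", path)
  }
  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) carries the real format in the extension;
  # for plain PCM layouts the container fields above are sufficient.
  fmt_code <- fmt$audio_format
  bd <- fmt$bit_depth
  x <- if (fmt_code == 3L || (fmt_code == 65534L && bd %in% c(32L, 64L))) {
    readBin(data_raw, "double", length(data_raw) / (bd / 8L), size = bd / 8L,
            endian = "little")
  } else if (bd == 8L) {
    (readBin(data_raw, "integer", length(data_raw), 1, signed = FALSE) - 128) / 128
  } else if (bd == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2L, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (bd == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    v / 8388608
  } else if (bd == 32L) {
    readBin(data_raw, "integer", length(data_raw) / 4L, 4, signed = TRUE,
            endian = "little") / 2147483648
  } else {
    stop("cannot decode audio (unsupported bit depth ", bd, "): ", path)
  }
  nc <- fmt$n_channels
  n <- length(x) %/% nc
  if (n == 0L) stop("empty audio: no complete frames in ", path)
  samples <- matrix(x[seq_len(n * nc)], nrow = nc)
  list(samples = samples, sample_rate = fmt$sample_rate,
       bit_depth = bd, n_channels = nc)
}

#' Write a 16-bit PCM RIFF/WAVE file
#'
#' @param samples Numeric vector (mono) or channels-by-n matrix in `[-1, 1]`.
#'   Values outside the range are clipped.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
write_wav <- function(samples, sample_rate, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  nc <- nrow(samples)
  x <- pmin(pmax(as.numeric(samples), -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                      # PCM
  writeBin(nc, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * nc * 2L), con, 4, endian = "little")
  writeBin(as.integer(nc * 2L), con, 2, endian = "little")     # block align
  writeBin(16L, con, 2, endian = "little")                     # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
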