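#' Read a RIFF/WAVE audio file
#'
#' Minimal reader for uncompressed WAV containers: 16- or 24-bit integer PCM
#' and 32-bit IEEE float streams. Integer samples are rescaled to the
#' \[-1, 1\] range. Multi-channel files are averaged to mono.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform] with the sample rate taken from the file header.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("malformed WAV: missing RIFF header", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("malformed WAV: missing WAVE id", call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2L))  # skip unknown chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("malformed WAV: no fmt chunk", call. = FALSE)
  if (is.null(data_raw) || length(data_raw) == 0) {
    stop("empty WAV data stream", call. = FALSE)
  }

  x <- switch(as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (fmt$bits == 16) {
        as.numeric(readBin(data_raw, "integer", length(data_raw) / 2,
                           size = 2, signed = TRUE, endian = "little")) / 32768
      } else if (fmt$bits == 24) {
        n <- length(data_raw) %/% 3
        b <- matrix(as.integer(data_raw[seq_len(3 * n)]), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        stop(sprintf("unsupported PCM bit depth: %d", fmt$bits), call. = FALSE)
      }
    },
    "3" = readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                  endian = "little"),
    stop(sprintf("unsupported WAV audio format code: %d", fmt$audio_format),
         call. = FALSE)
  )

  if (fmt$n_channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  waveform(x, fmt$sample_rate)
}

#' Write a waveform as an integer PCM WAV file
#'
#' @param wave A [waveform] with `|samples| <= 1`; callers must normalize
#'   before export (clipping input is an error, not silently truncated).
#' @param path Output path.
#' @param bit_depth Either 16 (default) or 24 bits per sample.
#' @return The path, invisibly.
#' @export
write_wav <- function(wave, path, bit_depth = 16) {
  assert_waveform(wave)
  if (max(abs(wave$samples)) > 1) {
    stop("samples exceed full scale; normalize before writing", call. = FALSE)
  }
  if (!bit_depth %in% c(16, 24)) stop("bit_depth must be 16 or 24", call. = FALSE)

  n <- length(wave$samples)
  bytes_per_sample <- bit_depth / 8
  data_size <- n * bytes_per_sample
  rate <- round(wave$sample_rate)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                    # PCM
  writeBin(1L, con, size = 2, endian = "little")                    # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per_sample), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")

  if (bit_depth == 16) {
    q <- as.integer(pmax(pmin(round(wave$samples * 32768), 32767), -32768))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    q <- pmax(pmin(round(wave$samples * 8388608), 8388607), -8388608)
    q <- ifelse(q < 0, q + 16777216, q)
    b <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}
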