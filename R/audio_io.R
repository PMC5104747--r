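# Minimal RIFF/WAV PCM reader and writer (16- or 24-bit, any channel
# count). Implemented directly over writeBin/readBin.

int_to_pcm_bytes <- function(x_int, bits) {
  if (bits == 16) {
    return(writeBin(as.integer(x_int), raw(), size = 2, endian = "little"))
  }
  # 24-bit: little-endian triplets from signed integers
  v <- as.integer(x_int)
  v[v < 0] <- v[v < 0] + 16777216L
  b0 <- v %% 256L
  b1 <- (v %/% 256L) %% 256L
  b2 <- (v %/% 65536L) %% 256L
  out <- raw(3 * length(v))
  out[seq(1, length(out), by = 3)] <- as.raw(b0)
  out[seq(2, length(out), by = 3)] <- as.raw(b1)
  out[seq(3, length(out), by = 3)] <- as.raw(b2)
  out
}

pcm_bytes_to_num <- function(bytes, bits) {
  if (bits == 16) {
    ints <- readBin(bytes, integer(), n = length(bytes) / 2, size = 2,
                    endian = "little", signed = TRUE)
    return(ints / 32767)
  }
  m <- matrix(as.integer(bytes), nrow = 3)
  v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
  v[v >= 8388608] <- v[v >= 8388608] - 16777216
  v / 8388607
}

#' Write rendered audio as a PCM WAV file
#'
#' @param audio A `rendered_audio`.
#' @param path Output path.
#' @param bits Bit depth, 16 (default) or 24.
#' @param metadata_path Optional path for a JSON sidecar recording the
#'   render metadata (seed, mapping constants).
#' @return `path`, invisibly.
#' @export
write_audio <- function(audio, path, bits = 16, metadata_path = NULL) {
  stopifnot(inherits(audio, "rendered_audio"), bits %in% c(16, 24))
  if (!is.character(path) || length(path) != 1 || !nzchar(path))
    stop("invalid output path")
  s <- audio$samples
  if (max(abs(s)) > 1) stop("samples exceed [-1, 1]")
  n_ch <- nrow(s)
  scale <- if (bits == 16) 32767 else 8388607
  interleaved <- round(as.vector(s) * scale)   # column-major = interleaved
  data_bytes <- int_to_pcm_bytes(interleaved, bits)
  block_align <- n_ch * bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(data_bytes)), con, size = 4,
           endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(audio$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$sample_rate * block_align), con, size = 4,
           endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(data_bytes)), con, size = 4, endian = "little")
  writeBin(data_bytes, con)
  if (!is.null(metadata_path))
    jsonlite::write_json(audio$meta, metadata_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Supports the 16- and 24-bit integer PCM files written by
#' [write_audio()].
#'
#' @param path Path to a WAV file.
#' @return A `rendered_audio`.
#' @export
read_audio <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_raw <- readBin(con, raw(), n = size)
      fmt <- list(
        format = readBin(fmt_raw[1:2], integer(), size = 2,
                         endian = "little"),
        n_ch = readBin(fmt_raw[3:4], integer(), size = 2,
                       endian = "little"),
        sr = readBin(fmt_raw[5:8], integer(), size = 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], integer(), size = 2,
                       endian = "little")
      )
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      bytes <- readBin(con, raw(), n = size)
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (fmt$format != 1) stop("only integer PCM supported")
  if (!fmt$bits %in% c(16, 24)) stop("only 16/24-bit PCM supported")
  x <- pcm_bytes_to_num(bytes, fmt$bits)
  samples <- matrix(x, nrow = fmt$n_ch)
  layout <- switch(as.character(fmt$n_ch), "1" = "mono", "2" = "stereo",
                   "8" = "ring8", "mono")
  rendered_audio(samples, fmt$sr, layout)
}
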