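#' Read an uncompressed WAVE file
#'
#' Reads RIFF/WAVE containers holding IEEE float32 samples (format tag 3,
#' the dataset's clip dialect) or integer PCM at 16, 24 or 32 bits (format
#' tag 1, plus the WAVE_FORMAT_EXTENSIBLE wrapper around either). Integer
#' PCM is rescaled to full-scale units by `2^(bits - 1)`, so a 16-bit
#' sample of 16384 reads as 0.5. Channels are de-interleaved into the
#' columns of the sample matrix.
#'
#' @param path path to a `.wav` file.
#' @param date,species,source_id optional provenance metadata to attach; by
#'   default `source_id` is the file path and, when the filename follows the
#'   clip naming grammar (see [parse_clip_name()]), date and species are
#'   recovered from it.
#' @return an [recording()] object.
#' @export
read_wave <- function(path, date = NULL, species = NULL, source_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")  # riff size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      if (length(body) < 16L) stop("truncated fmt chunk", call. = FALSE)
      fmt <- parse_fmt_chunk(body)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) {
        stop("truncated WAVE data chunk: expected ", size, " bytes, got ",
             length(data_raw), call. = FALSE)
      }
    } else {
      seek(con, size, origin = "current")
    }
    if (size %% 2L == 1L) seek(con, 1, origin = "current")  # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAVE file has no fmt chunk", call. = FALSE)
  if (is.null(data_raw)) stop("WAVE file has no data chunk", call. = FALSE)
  if (fmt$channels < 1L) stop("WAVE file reports zero channels", call. = FALSE)

  x <- decode_wave_samples(data_raw, fmt)
  n <- length(x) %/% fmt$channels
  mat <- matrix(x[seq_len(n * fmt$channels)], ncol = fmt$channels,
                byrow = TRUE)

  meta <- tryCatch(parse_clip_name(basename(path)),
                   error = function(e) NULL)
  recording(mat, rate = fmt$rate,
            date = date %||% (if (!is.null(meta)) meta$date else NA),
            species = species %||% (if (!is.null(meta)) meta$species else ""),
            source_id = source_id %||% path)
}

parse_fmt_chunk <- function(body) {
  u16 <- function(i) {
    sum(as.integer(body[i + 0:1]) * c(1L, 256L))
  }
  u32 <- function(i) {
    sum(as.numeric(body[i + 0:3]) * c(1, 256, 65536, 16777216))
  }
  tag <- u16(1L)
  out <- list(tag = tag, channels = u16(3L), rate = u32(5L),
              bits = u16(15L))
  if (tag == 65534L) {  # WAVE_FORMAT_EXTENSIBLE: subformat GUID at offset 24
    if (length(body) < 26L) stop("truncated extensible fmt chunk",
                                 call. = FALSE)
    out$tag <- u16(25L)
  }
  if (!out$tag %in% c(1L, 3L)) {
    stop("unsupported format tag ", out$tag,
         " (only integer PCM and IEEE float WAVE are supported)",
         call. = FALSE)
  }
  if (out$tag == 3L && out$bits != 32L) {
    stop("unsupported float sample width: ", out$bits, " bits",
         call. = FALSE)
  }
  if (out$tag == 1L && !out$bits %in% c(16L, 24L, 32L)) {
    stop("unsupported PCM sample width: ", out$bits, " bits", call. = FALSE)
  }
  out
}

decode_wave_samples <- function(raw, fmt) {
  if (fmt$tag == 3L) {
    return(readBin(raw, "numeric", length(raw) %/% 4L, size = 4L,
                   endian = "little"))
  }
  if (fmt$bits == 16L) {
    v <- readBin(raw, "integer", length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
    return(v / 32768)
  }
  if (fmt$bits == 32L) {
    v <- readBin(raw, "integer", length(raw) %/% 4L, size = 4L,
                 endian = "little")
    return(v / 2147483648)
  }
  # 24-bit: assemble little-endian triples by hand
  n <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
  v <- b[1L, ] + b[2L, ] * 256 + b[3L, ] * 65536
  v <- ifelse(v >= 8388608, v - 16777216, v)
  v / 8388608
}

#' Write a recording or clip as an IEEE float32 WAVE file
#'
#' `write_wave()` writes any recording to an explicit path. `write_clip()`
#' enforces the dataset clip contract (equal-length channels, finite
#' samples, length exactly `round(clip_ms/1000 * rate)` samples) and names
#' the file by the clip grammar
#' `<YYYY-MM-DD>_<Genus>_<species>_<NNNNNN>.wav`. A 2500 ms, 4-channel,
#' 16 kHz float32 clip has an audio payload of 4 x 40000 x 4 bytes =
#' 625 KiB, the dataset's nominal per-file size.
#'
#' @param x a [recording()] or [clip()].
#' @param path output file path.
#' @return the path written, invisibly for `write_wave()`, visibly for
#'   `write_clip()`.
#' @export
write_wave <- function(x, path) {
  stopifnot(inherits(x, "insect_recording"))
  if (!all(is.finite(x$samples))) {
    stop("refusing to write non-finite samples", call. = FALSE)
  }
  n <- nrow(x$samples)
  ch <- ncol(x$samples)
  interleaved <- as.numeric(t(x$samples))
  data_size <- n * ch * 4L

  con <- file(path, "wb")
  on.exit(close(con))
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                                endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                                endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w_u32(4L + 24L + 12L + 8L + data_size)  # WAVE + fmt(16) + fact + data hdr
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w_u32(16L)
  w_u16(3L)                      # IEEE float
  w_u16(ch)
  w_u32(round(x$rate))
  w_u32(round(x$rate) * ch * 4L) # byte rate
  w_u16(ch * 4L)                 # block align
  w_u16(32L)
  writeChar("fact", con, eos = NULL)
  w_u32(4L)
  w_u32(n)
  writeChar("data", con, eos = NULL)
  w_u32(data_size)
  writeBin(interleaved, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_wave
#' @param out_dir output directory (must exist and be writable).
#' @param clip_ms expected clip length in milliseconds used to check the
#'   clip invariant before anything is written.
#' @export
write_clip <- function(x, out_dir, clip_ms = 2500) {
  stopifnot(inherits(x, "insect_clip"))
  validate_clip(x, clip_ms = clip_ms)
  if (!dir.exists(out_dir)) {
    stop("output directory does not exist: ", out_dir, call. = FALSE)
  }
  fname <- format_clip_name(x$date, x$species, x$index)
  path <- file.path(out_dir, fname)
  write_wave(x, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
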