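#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader for PCM (8/16/24/32-bit integer) and IEEE
#' float-32 audio. Multi-channel files are reduced to mono by averaging
#' the channels; integer samples are scaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @param label,domain_id,record_id Optional metadata attached to the
#'   returned recording; `record_id` defaults to the file name without
#'   extension.
#' @return An [audio_recording()] with `fs` taken from the file header.
#' @export
read_wav <- function(path, label = NA_character_, domain_id = NA_character_,
                     record_id = NULL) {
  if (!file.exists(path))
    stop("read_wav: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("read_wav: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("read_wav: not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        fs       = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1L, 2L, signed = FALSE,
                           endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("read_wav: corrupt WAV (missing fmt/data chunk): ", path)

  bytes_per <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes_per
  if (n_total < 1L)
    stop("read_wav: zero-length audio: ", path)

  x <- if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n_total, size = 4L, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n_total, size = 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 8L) {
    (readBin(data_raw, "integer", n_total, size = 1L, signed = FALSE,
             endian = "little") - 128) / 128
  } else if (fmt$format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", n_total, size = 4L, endian = "little") /
      2147483648
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3L)
    v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else {
    stop("read_wav: unsupported WAV encoding (format ", fmt$format,
         ", ", fmt$bits, " bits): ", path)
  }

  if (fmt$channels > 1L) {
    n_frames <- n_total %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$channels)],
                         nrow = fmt$channels))
  }
  if (is.null(record_id))
    record_id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  audio_recording(x, fmt$fs, label = label, domain_id = domain_id,
                  record_id = record_id)
}

#' Write a WAV file
#'
#' Writes a mono recording as 16-bit PCM (default) or IEEE float-32.
#' PCM samples are clipped to `[-1, 1]` and quantised.
#'
#' @param rec An [audio_recording()] or numeric vector.
#' @param path Output path.
#' @param fs Sampling rate, required when `rec` is a bare vector.
#' @param encoding `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, fs = NULL, encoding = c("pcm16", "float32")) {
  encoding <- match.arg(encoding)
  if (inherits(rec, "audio_recording")) {
    x <- rec$samples; fs <- rec$fs
  } else {
    if (is.null(fs)) stop("write_wav: fs required for a bare vector")
    x <- as.numeric(rec)
  }
  n <- length(x)
  if (encoding == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    q <- as.integer(round(pmin(pmax(x, -1), 32767 / 32768) * 32768))
  } else {
    fmt_code <- 3L; bits <- 32L
  }
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")                # mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (encoding == "pcm16") {
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `record_id`, `path`, `label`,
#' `domain_id` describing a heart-sound dataset on disk.
#'
#' @param path CSV path.
#' @return A data.frame with the four manifest columns.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "path", "label", "domain_id")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("read_manifest: missing columns: ", paste(miss, collapse = ", "))
  m
}
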