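#' Construct an audio recording
#'
#' Light container for a mono sampled waveform with its rate, encoding and
#' caller/call identity. Amplitudes are dimensionless, full scale being 1.0.
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param rate Sampling rate in Hz (telephone recordings are 8000 Hz).
#' @param encoding `"float32"` or `"pcm16"` — the encoding the samples came
#'   from (or should be written back to).
#' @param call_id,caller_id Opaque identifiers.
#' @param sex `"male"`, `"female"` or `NA`.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, rate, encoding = c("float32", "pcm16"),
                            call_id = NA_character_, caller_id = NA_character_,
                            sex = NA_character_) {
  encoding <- match.arg(encoding)
  stopifnot(is.numeric(samples), length(rate) == 1L, rate > 0)
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         encoding = encoding, call_id = call_id, caller_id = caller_id,
         sex = sex),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %s: %d samples @ %g Hz (%.2f s, %s)\n",
              x$call_id %||% "?", length(x$samples), x$rate,
              length(x$samples) / x$rate, x$encoding))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read a mono RIFF/WAVE file
#'
#' Supports 16-bit PCM (format code 1) and 32-bit IEEE float (format code 3),
#' single channel. PCM samples are scaled by 1/32768 so full-scale negative
#' maps to -1.0 exactly.
#'
#' @param path Path to a `.wav` file.
#' @inheritParams audio_recording
#' @return An [audio_recording()].
#' @export
read_wav <- function(path, call_id = NA_character_, caller_id = NA_character_,
                     sex = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        code     = readBin(body[1:2], "integer", 1L, 2L, endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, endian = "little"),
        rate     = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1L, 2L, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2L)  # skip chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAVE header in ", path)
  if (fmt$channels != 1L)
    stop("expected mono audio, got ", fmt$channels, " channels")

  if (fmt$code == 1L && fmt$bits == 16L) {
    ints <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
                    signed = TRUE, endian = "little")
    samples <- ints / 32768
    enc <- "pcm16"
  } else if (fmt$code == 3L && fmt$bits == 32L) {
    samples <- readBin(data_raw, "double", length(data_raw) %/% 4L, 4L,
                       endian = "little")
    enc <- "float32"
  } else {
    stop("unsupported WAVE format: code ", fmt$code, ", ", fmt$bits, " bits")
  }
  audio_recording(samples, fmt$rate, enc, call_id, caller_id, sex)
}

#' Write a mono RIFF/WAVE file
#'
#' @param rec An [audio_recording()].
#' @param path Output path.
#' @param encoding Encoding to write; defaults to the recording's own.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, encoding = rec$encoding) {
  stopifnot(inherits(rec, "audio_recording"))
  encoding <- match.arg(encoding, c("float32", "pcm16"))
  n <- length(rec$samples)
  bytes_per <- if (encoding == "pcm16") 2L else 4L
  data_len <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  code <- if (encoding == "pcm16") 1L else 3L
  writeBin(code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                       # mono
  writeBin(as.integer(rec$rate), con, 4L, endian = "little")
  writeBin(as.integer(rec$rate * bytes_per), con, 4L, endian = "little")
  writeBin(bytes_per, con, 2L, endian = "little")
  writeBin(8L * bytes_per, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, 4L, endian = "little")
  if (encoding == "pcm16") {
    ints <- as.integer(pmax(-32768, pmin(32767, round(rec$samples * 32768))))
    writeBin(ints, con, 2L, endian = "little")
  } else {
    writeBin(rec$samples, con, 4L, endian = "little")
  }
  invisible(path)
}

#' Parse an Audacity label track into segment annotations
#'
#' Audacity exports labels as TSV rows `start<TAB>end<TAB>label` in seconds.
#' Here the label carries the segment's distress-thermometer rating (an
#' integer 0--10), dichotomized at `cutoff`: rating >= cutoff is "high".
#'
#' @param path Path to a label-track TSV.
#' @param cutoff Dichotomization cutoff on the 0--10 rating (default 4, the
#'   clinical distress-thermometer threshold).
#' @param call_id Identifier attached to every row.
#' @return A tibble with columns `segment_id`, `call_id`, `start_s`, `end_s`,
#'   `distress_rating`, `distress_label` (factor low/high).
#' @export
read_audacity_labels <- function(path, cutoff = 4, call_id = NA_character_) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           col.names = c("start", "end", "label"))
  start_s <- as.numeric(raw$start)
  end_s <- as.numeric(raw$end)
  rating <- suppressWarnings(as.integer(raw$label))
  if (anyNA(start_s) || anyNA(end_s))
    stop("unparseable start/end time in ", path)
  if (anyNA(rating) || any(rating < 0 | rating > 10))
    stop("label not an integer rating in 0..10 in ", path)
  if (any(end_s <= start_s))
    stop("segment end <= start at row(s) ",
         paste(which(end_s <= start_s), collapse = ", "))
  tibble::tibble(
    segment_id = paste0(call_id %||% "call", "_seg", seq_along(start_s)),
    call_id = call_id,
    start_s = start_s, end_s = end_s,
    distress_rating = rating,
    distress_label = factor(ifelse(rating >= cutoff, "high", "low"),
                            levels = c("low", "high"))
  )
}

#' Quantize a recording to the 16-bit PCM grid
#'
#' Samples are rounded to the nearest multiple of 1/32768 (clipped at the
#' positive rail) and returned rescaled to `[-1, 1]`; idempotent on input
#' that is already on the grid.
#'
#' @param rec An [audio_recording()].
#' @return The recording with `encoding = "pcm16"`.
#' @export
to_pcm16 <- function(rec) {
  stopifnot(inherits(rec, "audio_recording"))
  q <- pmax(-32768, pmin(32767, round(rec$samples * 32768)))
  rec$samples <- q / 32768
  rec$encoding <- "pcm16"
  rec
}

#' Mean-remove and pre-emphasize a recording
#'
#' Removes the DC component and applies the first-order pre-emphasis filter
#' `y[t] = x'[t] - alpha * x'[t-1]` (with `x'[-1] = 0`), boosting high
#' frequencies ahead of spectral analysis.
#'
#' @param rec An [audio_recording()].
#' @param alpha Pre-emphasis coefficient in `[0, 1)`; 0.97 is the standard
#'   speech value.
#' @return The filtered recording.
#' @export
normalize_preemphasize <- function(rec, alpha = 0.97) {
  stopifnot(inherits(rec, "audio_recording"))
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)")
  x <- rec$samples - mean(rec$samples)
  rec$samples <- x - alpha * c(0, x[-length(x)])
  rec
}

#' Cut a recording into overlapping windowed frames
#'
#' Frames are `frame_ms` long with fractional `overlap`, multiplied by a
#' Blackman window. Trailing samples that do not fill a frame are discarded;
#' frame times are frame centers.
#'
#' @param rec An [audio_recording()].
#' @param frame_ms Frame length in milliseconds (default 40).
#' @param overlap Fractional overlap of consecutive frames (default 0.5).
#' @return A `frame_series`: list with `frames` (n_frames x frame_len matrix),
#'   `frame_len`, `hop`, `rate`, `times` (centers, s), `window`, and a
#'   `silent_mask` initialized to all-FALSE.
#' @export
frame_signal <- function(rec, frame_ms = 40, overlap = 0.5) {
  stopifnot(inherits(rec, "audio_recording"))
  frame_len <- round(frame_ms / 1000 * rec$rate)
  hop <- as.integer(round(frame_len * (1 - overlap)))
  n <- length(rec$samples)
  if (n < frame_len)
    stop("signal shorter than one frame (", n, " < ", frame_len, " samples)")
  n_frames <- floor((n - frame_len) / hop) + 1
  w <- signal::blackman(frame_len)
  starts <- (seq_len(n_frames) - 1L) * hop
  raw <- matrix(0, nrow = n_frames, ncol = frame_len)
  for (i in seq_len(n_frames)) {
    raw[i, ] <- rec$samples[(starts[i] + 1):(starts[i] + frame_len)]
  }
  frames <- sweep(raw, 2L, w, `*`)
  structure(
    list(frames = frames, raw = raw, frame_len = as.integer(frame_len),
         hop = hop, rate = rec$rate, window = "blackman",
         times = (starts + frame_len / 2) / rec$rate,
         silent_mask = rep(FALSE, n_frames)),
    class = "frame_series"
  )
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames of %d samples (hop %d, %s window), %d silent\n",
              nrow(x$frames), x$frame_len, x$hop, x$window, sum(x$silent_mask)))
  invisible(x)
}

#' Mark silent frames by an RMS threshold
#'
#' A frame is silent when its RMS level in dBFS (relative to full scale 1.0)
#' is below `threshold_dbfs`. Raising the threshold can only mark more
#' frames silent. Downstream feature extraction drops silent frames.
#'
#' @param series A `frame_series` from [frame_signal()].
#' @param threshold_dbfs Silence threshold in dBFS (default -50).
#' @return The series with `silent_mask` updated.
#' @export
detect_silence <- function(series, threshold_dbfs = -50) {
  stopifnot(inherits(series, "frame_series"))
  rms <- sqrt(rowMeans(series$raw^2))
  db <- ifelse(rms > 0, 20 * log10(rms), -Inf)
  series$silent_mask <- db < threshold_dbfs
  series
}
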