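#' Canonical per-frame feature names
#'
#' The 21 acoustic variables computed for every non-silent 40-ms frame:
#' loudness/energy (`rms_db`, `loudness`), spectral shape (`spectral_centroid`,
#' `peak_freq`, `dominant_freq`, quartile frequencies, `spectral_slope`,
#' `entropy`), formants (`f1_freq` .. `f3_width`), harmonicity
#' (`noise_to_harmonics`, `subharmonic_depth`) and sequence context
#' (`spectral_flux`, `spectral_novelty`, `roughness`).
#'
#' @return Character vector of feature column names.
#' @export
distress_features <- function() {
  c("rms_db", "dominant_freq", "entropy",
    "f1_freq", "f1_width", "f2_freq", "f2_width", "f3_freq", "f3_width",
    "spectral_flux", "noise_to_harmonics", "loudness", "spectral_novelty",
    "peak_freq", "q25_freq", "q50_freq", "q75_freq", "roughness",
    "spectral_centroid", "spectral_slope", "subharmonic_depth")
}

#' One-sided power spectrum of a frame
#'
#' Zero-pads the (windowed) frame to `nfft` and returns the one-sided power
#' spectrum scaled so that `sum(power)` equals the time-domain energy
#' `sum(frame^2)` (Parseval).
#'
#' @param frame Numeric vector (one windowed frame).
#' @param rate Sampling rate, Hz.
#' @param nfft FFT length, `>= length(frame)` (default 512).
#' @return List with `freqs` (Hz, length `nfft/2 + 1`), `power` (linear) and
#'   `magnitude_db`.
#' @export
frame_spectrum <- function(frame, rate, nfft = 512) {
  n <- length(frame)
  if (n == 0L) stop("empty frame")
  if (nfft < n) stop("nfft (", nfft, ") must be >= frame length (", n, ")")
  x <- c(frame, rep(0, nfft - n))
  X <- stats::fft(x)
  half <- nfft %/% 2L
  p <- Mod(X[1:(half + 1L)])^2 / nfft
  # fold negative frequencies into bins 2..nfft/2
  p[2:half] <- 2 * p[2:half]
  list(freqs = (0:half) * rate / nfft,
       power = p,
       magnitude_db = 10 * log10(pmax(p, .Machine$double.xmin)))
}

#' Frame RMS amplitude in dBFS
#'
#' `20 * log10(RMS)` relative to full scale 1.0; `-Inf` for an all-zero frame
#' (such frames should already be silence-masked).
#'
#' @param frame Numeric vector of raw (unwindowed) samples.
#' @return Scalar dBFS value.
#' @export
amplitude_rms_db <- function(frame) {
  rms <- sqrt(mean(frame^2))
  if (rms == 0) -Inf else 20 * log10(rms)
}

#' Spectral-shape features of one frame spectrum
#'
#' Computes the power-weighted centroid, the argmax peak frequency, the
#' dominant frequency (lowest local peak whose power reaches
#' `prominence` of the global maximum), cumulative-power quartile
#' frequencies, the least-squares slope of dB magnitude vs frequency
#' (dB/kHz), and the Wiener entropy (geometric over arithmetic mean of
#' power, 0 = pure tone, 1 = white noise).
#'
#' @param spec A spectrum from [frame_spectrum()].
#' @param band Two-element analysis band in Hz (default `c(0, 4000)`).
#' @param prominence Fraction of the global maximum a local peak must reach
#'   to count as dominant (default 0.1).
#' @return Named list: `spectral_centroid`, `peak_freq`, `dominant_freq`,
#'   `q25_freq`, `q50_freq`, `q75_freq`, `spectral_slope`, `entropy`.
#' @export
spectral_shape <- function(spec, band = c(0, 4000), prominence = 0.1) {
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  f <- spec$freqs[sel]
  p <- spec$power[sel]
  tot <- sum(p)
  if (tot <= 0) stop("zero spectrum: spectral shape undefined")

  centroid <- sum(f * p) / tot
  peak <- f[which.max(p)]

  # dominant = lowest local maximum with power >= prominence * global max
  thr <- prominence * max(p)
  n <- length(p)
  is_peak <- p >= thr &
    p >= c(-Inf, p[-n]) &        # >= left neighbor
    p >= c(p[-1], -Inf)          # >= right neighbor
  dominant <- if (any(is_peak)) f[which(is_peak)[1]] else peak

  cum <- cumsum(p) / tot
  qf <- function(q) f[which(cum >= q)[1]]

  pos <- p > 0
  slope <- if (sum(pos) >= 2) {
    fit <- stats::lm.fit(cbind(1, f[pos] / 1000),
                         10 * log10(p[pos]))
    fit$coefficients[2]
  } else NA_real_
  ent <- exp(mean(log(p[pos]))) / mean(p[pos])

  list(spectral_centroid = centroid, peak_freq = peak,
       dominant_freq = dominant,
       q25_freq = qf(0.25), q50_freq = qf(0.50), q75_freq = qf(0.75),
       spectral_slope = unname(slope),
       entropy = min(1, max(0, ent)))
}

#' Formant frequencies and bandwidths by Burg LPC
#'
#' Fits an order-`order` autoregressive model (Burg), converts complex pole
#' pairs to frequencies `f = angle * rate / (2*pi)` and bandwidths
#' `b = -(rate/pi) * log|pole|`, sorts ascending, and returns the first
#' three in `(90, rate/2 - 50)` Hz. Poles broader than `bw_max` are
#' rejected as spurious (they model overall spectral tilt, not
#' resonances). Missing formants are `NA`.
#'
#' @param frame Numeric vector (non-silent frame).
#' @param rate Sampling rate, Hz.
#' @param order LPC order (default 10, the `2 + rate/1000` heuristic at 8 kHz).
#' @param bw_max Maximum admissible formant bandwidth, Hz (default 400).
#' @return Named list `f1_freq`, `f1_width`, `f2_freq`, `f2_width`,
#'   `f3_freq`, `f3_width`.
#' @export
formants_lpc <- function(frame, rate, order = 10, bw_max = 400) {
  out <- list(f1_freq = NA_real_, f1_width = NA_real_,
              f2_freq = NA_real_, f2_width = NA_real_,
              f3_freq = NA_real_, f3_width = NA_real_)
  a <- tryCatch({
    fit <- stats::ar.burg(frame, aic = FALSE, order.max = order,
                          demean = TRUE)
    fit$ar
  }, error = function(e) NULL)
  if (is.null(a) || length(a) < 2L) return(out)

  # roots x of 1 - a1 x - ... - ap x^p ; poles z = 1/x
  rts <- tryCatch(polyroot(c(1, -a)), error = function(e) complex(0))
  if (!length(rts)) return(out)
  z <- 1 / rts
  z <- z[Im(z) > 0]
  if (!length(z)) return(out)
  freq <- Arg(z) * rate / (2 * pi)
  bw <- -(rate / pi) * log(Mod(z))
  ok <- freq > 90 & freq < rate / 2 - 50 & bw > 0 & bw < bw_max
  freq <- freq[ok]; bw <- bw[ok]
  if (!length(freq)) return(out)
  o <- order(freq)
  freq <- freq[o]; bw <- bw[o]
  for (i in seq_len(min(3L, length(freq)))) {
    out[[paste0("f", i, "_freq")]] <- freq[i]
    out[[paste0("f", i, "_width")]] <- bw[i]
  }
  out
}

#' Harmonicity features from the normalized autocorrelation
#'
#' Searches the autocorrelation in the pitch-period lag band
#' `[rate/pitch_ceiling, rate/pitch_floor]`. The best normalized peak `r*`
#' gives the noise-to-harmonics ratio `(1 - r*) / r*` (clipped to
#' `[0, 10]`) and an f0 candidate. Subharmonic depth is the dB prominence
#' of the strongest spectral peak at a half-integer multiple of f0 above
#' the neighboring inter-harmonic floor (0 when no subharmonic is present);
#' it grows with period-doubling alternation depth.
#'
#' @param frame Numeric vector (non-silent frame).
#' @param rate Sampling rate, Hz.
#' @param pitch_floor,pitch_ceiling f0 search band, Hz (default 75--300).
#' @param spec Optional precomputed [frame_spectrum()] (recomputed if NULL).
#' @return Named list `noise_to_harmonics`, `subharmonic_depth`, `f0`.
#' @export
harmonicity <- function(frame, rate, pitch_floor = 75, pitch_ceiling = 300,
                        spec = NULL) {
  x <- frame - mean(frame)
  n <- length(x)
  r0 <- sum(x^2)
  miss <- list(noise_to_harmonics = NA_real_, subharmonic_depth = NA_real_,
               f0 = NA_real_)
  if (r0 == 0) return(miss)
  lmin <- max(2L, floor(rate / pitch_ceiling))
  lmax <- min(n - 1L, ceiling(rate / pitch_floor))
  if (lmax <= lmin) return(miss)
  # autocorrelation via FFT
  nfft2 <- 2^ceiling(log2(2 * n))
  ac <- Re(stats::fft(Mod(stats::fft(c(x, rep(0, nfft2 - n))))^2,
                      inverse = TRUE))[1:(lmax + 1L)] / nfft2
  rnorm_ <- ac / ac[1]
  lags <- lmin:lmax
  best <- which.max(rnorm_[lags + 1L])
  rstar <- rnorm_[lags[best] + 1L]
  if (rstar <= 0) return(miss)
  f0 <- rate / lags[best]
  nhr <- min(10, max(0, (1 - rstar) / rstar))

  if (is.null(spec)) spec <- frame_spectrum(frame, rate)
  depth <- subharmonic_depth_db(spec, f0)
  list(noise_to_harmonics = nhr, subharmonic_depth = depth, f0 = f0)
}

# dB prominence of the strongest half-integer-harmonic peak above the
# inter-harmonic valley floor beside it (left/right medians, min of the
# two so a neighboring harmonic skirt cannot masquerade as the floor).
subharmonic_depth_db <- function(spec, f0) {
  fmax <- max(spec$freqs)
  kmax <- min(5.5, floor(fmax / f0) - 0.5)
  if (kmax < 0.5) return(0)
  depth <- 0
  for (k in seq(0.5, kmax, by = 1)) {
    fc <- k * f0
    win <- spec$freqs >= fc - 0.2 * f0 & spec$freqs <= fc + 0.2 * f0
    left <- spec$freqs >= fc - 0.42 * f0 & spec$freqs <= fc - 0.25 * f0
    right <- spec$freqs >= fc + 0.25 * f0 & spec$freqs <= fc + 0.42 * f0
    if (!any(win) || (!any(left) && !any(right))) next
    pk <- max(spec$power[win])
    floors <- c(if (any(left)) stats::median(spec$power[left]),
                if (any(right)) stats::median(spec$power[right]))
    floor_p <- min(floors)
    if (pk > 0 && floor_p > 0)
      depth <- max(depth, 10 * log10(pk / floor_p))
  }
  depth
}

# Zwicker critical-band edges (Hz), truncated to the analysis band at use.
.bark_edges <- c(0, 100, 200, 300, 400, 510, 630, 770, 920, 1080, 1270,
                 1480, 1720, 2000, 2320, 2700, 3150, 3700, 4400, 5300,
                 6400, 7700, 9500, 12000, 15500)

#' Psychoacoustic loudness in sone
#'
#' Integrates spectral power over Zwicker critical bands within
#' `[0, rate/2]`, maps each band by Stevens' power law (specific loudness
#' proportional to intensity^0.3) and sums. Homogeneous of degree 0.3 in
#' signal power; 0 for a silent frame.
#'
#' @param spec A spectrum from [frame_spectrum()].
#' @param rate Sampling rate, Hz.
#' @return Scalar loudness (sone, model scale).
#' @export
loudness_sone <- function(spec, rate) {
  edges <- .bark_edges[.bark_edges <= rate / 2]
  if (length(edges) < 2) edges <- c(0, rate / 2)
  band <- findInterval(spec$freqs, edges, rightmost.closed = TRUE)
  bp <- tapply(spec$power, band, sum)
  sum(bp^0.3)
}

#' Sequence-context features within one segment
#'
#' Per-frame spectral flux (Euclidean distance between consecutive
#' unit-normalized spectra; first frame 0), spectral novelty (checkerboard
#' kernel correlation on the local cosine self-similarity matrix, edges
#' padded by replication) and roughness (proportion of amplitude-envelope
#' modulation energy in 30--150 Hz over the local window). Context never
#' crosses segment boundaries; a single-frame segment gets all three = 0.
#'
#' @param power_mat n_frames x n_bins matrix of frame power spectra
#'   (consecutive non-silent frames of one segment).
#' @param raw_mat n_frames x frame_len matrix of the matching raw samples.
#' @param rate Sampling rate, Hz.
#' @param hop Hop size in samples between consecutive frames.
#' @param window_frames Odd local window width in frames (default 5).
#' @return Tibble with columns `spectral_flux`, `spectral_novelty`,
#'   `roughness`, one row per frame.
#' @export
sequence_features <- function(power_mat, raw_mat, rate, hop,
                              window_frames = 5) {
  n <- nrow(power_mat)
  if (n == 0L) return(tibble::tibble(spectral_flux = numeric(0),
                                     spectral_novelty = numeric(0),
                                     roughness = numeric(0)))
  norms <- sqrt(rowSums(power_mat^2))
  norms[norms == 0] <- 1
  U <- power_mat / norms

  flux <- c(0, sqrt(rowSums((U[-1, , drop = FALSE] -
                             U[-n, , drop = FALSE])^2)))

  w <- window_frames
  half <- w %/% 2
  kern <- outer(seq(-half, half), seq(-half, half),
                function(i, j) sign(i) * sign(j)) *
    outer(stats::dnorm(seq(-half, half), sd = half),
          stats::dnorm(seq(-half, half), sd = half))
  pad <- function(i) pmin(pmax(i, 1L), n)
  novelty <- numeric(n)
  roughness <- numeric(n)
  if (n >= 2) {
    for (t in seq_len(n)) {
      idx <- pad(t + seq(-half, half))
      S <- U[idx, , drop = FALSE] %*% t(U[idx, , drop = FALSE])
      novelty[t] <- max(0, sum(kern * S))
      # contiguous sample span: first `hop` samples of each frame + tail
      span <- c(t(raw_mat[idx[-w], seq_len(hop), drop = FALSE]),
                raw_mat[idx[w], ])
      env <- abs(span) - mean(abs(span))
      ms <- Mod(stats::fft(env))^2
      nb <- length(env)
      fm <- (seq_len(nb) - 1) * rate / nb
      tot_band <- fm > 0 & fm <= rate / 2
      mod_band <- fm >= 30 & fm <= 150
      tot <- sum(ms[tot_band])
      roughness[t] <- if (tot > 0) sum(ms[mod_band]) / tot else 0
    }
  }
  tibble::tibble(spectral_flux = flux, spectral_novelty = novelty,
                 roughness = roughness)
}

#' Default feature-extraction configuration
#'
#' @param alpha Pre-emphasis coefficient.
#' @param silence_dbfs Frame-RMS silence threshold, dBFS.
#' @param frame_ms,overlap Framing parameters.
#' @param nfft FFT length.
#' @param lpc_order LPC order for formant estimation.
#' @param pitch_floor,pitch_ceiling f0 search band, Hz.
#' @param band Spectral analysis band, Hz.
#' @param window_frames Sequence-context window, frames.
#' @return A named list.
#' @export
feature_config <- function(alpha = 0.97, silence_dbfs = -50, frame_ms = 40,
                           overlap = 0.5, nfft = 512, lpc_order = 10,
                           pitch_floor = 75, pitch_ceiling = 300,
                           band = c(0, 4000), window_frames = 5) {
  list(alpha = alpha, silence_dbfs = silence_dbfs, frame_ms = frame_ms,
       overlap = overlap, nfft = nfft, lpc_order = lpc_order,
       pitch_floor = pitch_floor, pitch_ceiling = pitch_ceiling,
       band = band, window_frames = window_frames)
}

#' Extract the per-frame feature table from annotated recordings
#'
#' For each recording: quantize to PCM16, mean-remove and pre-emphasize;
#' for each annotated segment: frame into overlapping Blackman windows,
#' drop silent frames, and compute the 21 features of
#' [distress_features()]. The segment's dichotomized distress label is
#' broadcast to all its frames; caller id and sex are attached.
#'
#' @param recordings A single [audio_recording()] or a list of them.
#' @param annotations Tibble as from [read_audacity_labels()] (one or more
#'   calls, matched to recordings by `call_id`).
#' @param config List from [feature_config()].
#' @return A tibble: `caller_id`, `call_id`, `sex`, `segment_id`,
#'   `distress_rating`, `distress_label`, `time`, then one column per
#'   feature. One row per non-silent frame.
#' @export
extract_features <- function(recordings, annotations,
                             config = feature_config()) {
  if (inherits(recordings, "audio_recording")) recordings <- list(recordings)
  ids <- vapply(recordings, function(r) r$call_id, character(1))
  missing_calls <- setdiff(unique(annotations$call_id), ids)
  if (length(missing_calls))
    stop("annotations reference unknown call(s): ",
         paste(missing_calls, collapse = ", "))

  res <- purrr::map_dfr(recordings, function(rec) {
    if (rec$rate != 8000)
      warning("recording ", rec$call_id, " is not 8 kHz (", rec$rate,
              " Hz); features computed over [0, rate/2]")
    ann <- dplyr::filter(annotations, .data$call_id == rec$call_id)
    if (nrow(ann) == 0L) return(NULL)
    dur <- length(rec$samples) / rec$rate
    bad <- ann$start_s < 0 | ann$end_s > dur + 1e-9
    if (any(bad))
      stop("annotation outside audio bounds for segment(s): ",
           paste(ann$segment_id[bad], collapse = ", "))
    rec <- normalize_preemphasize(to_pcm16(rec), config$alpha)

    purrr::map_dfr(seq_len(nrow(ann)), function(i) {
      seg <- ann[i, ]
      i0 <- floor(seg$start_s * rec$rate) + 1
      i1 <- min(length(rec$samples), ceiling(seg$end_s * rec$rate))
      sub <- audio_recording(rec$samples[i0:i1], rec$rate, "float32",
                             rec$call_id, rec$caller_id, rec$sex)
      fl <- round(config$frame_ms / 1000 * rec$rate)
      if (length(sub$samples) < fl) {
        warning("segment ", seg$segment_id, " shorter than one frame; skipped")
        return(NULL)
      }
      series <- frame_signal(sub, config$frame_ms, config$overlap)
      series <- detect_silence(series, config$silence_dbfs)
      keep <- which(!series$silent_mask)
      if (!length(keep)) {
        warning("segment ", seg$segment_id, " is fully silent; skipped")
        return(NULL)
      }
      frame_features(series, keep, rec, seg, config)
    })
  })
  tibble::as_tibble(res)
}

# Feature computation for the kept frames of one segment's frame series.
frame_features <- function(series, keep, rec, seg, config) {
  specs <- lapply(keep, function(j)
    frame_spectrum(series$frames[j, ], series$rate, config$nfft))
  power_mat <- do.call(rbind, lapply(specs, `[[`, "power"))

  per_frame <- purrr::map_dfr(seq_along(keep), function(m) {
    j <- keep[m]
    sp <- specs[[m]]
    shape <- spectral_shape(sp, config$band)
    fmt <- formants_lpc(series$frames[j, ], series$rate, config$lpc_order)
    # autocorrelation on the raw frame: the analysis window's taper would
    # bias long-lag correlation downward; the windowed spectrum is still
    # the right substrate for the subharmonic search
    hm <- harmonicity(series$raw[j, ], series$rate,
                      config$pitch_floor, config$pitch_ceiling, spec = sp)
    tibble::tibble(
      time = seg$start_s + series$times[j],
      rms_db = amplitude_rms_db(series$raw[j, ]),
      dominant_freq = shape$dominant_freq, entropy = shape$entropy,
      f1_freq = fmt$f1_freq, f1_width = fmt$f1_width,
      f2_freq = fmt$f2_freq, f2_width = fmt$f2_width,
      f3_freq = fmt$f3_freq, f3_width = fmt$f3_width,
      noise_to_harmonics = hm$noise_to_harmonics,
      loudness = loudness_sone(sp, series$rate),
      peak_freq = shape$peak_freq,
      q25_freq = shape$q25_freq, q50_freq = shape$q50_freq,
      q75_freq = shape$q75_freq,
      spectral_centroid = shape$spectral_centroid,
      spectral_slope = shape$spectral_slope,
      subharmonic_depth = hm$subharmonic_depth)
  })
  seq_f <- sequence_features(power_mat, series$raw[keep, , drop = FALSE],
                             series$rate, series$hop, config$window_frames)
  dplyr::bind_cols(
    tibble::tibble(caller_id = rec$caller_id, call_id = rec$call_id,
                   sex = rec$sex, segment_id = seg$segment_id,
                   distress_rating = seg$distress_rating,
                   distress_label = seg$distress_label,
                   .rows = nrow(per_frame)),
    per_frame, seq_f
  )[, c("caller_id", "call_id", "sex", "segment_id", "distress_rating",
        "distress_label", "time", distress_features())]
}
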