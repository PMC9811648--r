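rate <- 8000

test_that("frame_spectrum satisfies Parseval and localizes tones", {
  set.seed(1)
  fr <- rnorm(320) * blackman320()
  sp <- frame_spectrum(fr, rate)
  expect_equal(sum(sp$power), sum(fr^2), tolerance = 1e-9)
  expect_length(sp$freqs, 257)
  expect_equal(diff(sp$freqs)[1], rate / 512)

  expect_true(all(frame_spectrum(rep(0, 320), rate)$power == 0))

  sp1 <- frame_spectrum(tone(1000, 0.04) * blackman320(), rate)
  expect_lt(abs(sp1$freqs[which.max(sp1$power)] - 1000), rate / 512)

  expect_error(frame_spectrum(rnorm(600), rate, nfft = 512), "nfft")
})

test_that("amplitude_rms_db follows the dB laws", {
  square <- rep(c(1, -1), 160)
  expect_equal(amplitude_rms_db(square), 0)
  expect_equal(amplitude_rms_db(tone(1000, 0.04)), -3.01, tolerance = 0.02)
  x <- rnorm(320)
  expect_equal(amplitude_rms_db(x / 2) - amplitude_rms_db(x), -20 * log10(2),
               tolerance = 1e-9)
  expect_identical(amplitude_rms_db(rep(0, 320)), -Inf)
})

test_that("spectral_shape: tone, flat-spectrum and two-tone identities", {
  bin <- rate / 512
  sh <- spectral_shape(frame_spectrum(tone(1000, 0.04) * blackman320(),
                                      rate))
  expect_lt(abs(sh$spectral_centroid - 1000), bin)
  expect_lt(abs(sh$peak_freq - 1000), bin)
  expect_lt(abs(sh$dominant_freq - 1000), bin)
  expect_lt(abs(sh$q50_freq - 1000), bin)
  expect_lt(sh$entropy, 1e-3)

  flat <- list(freqs = seq(0, 4000, length.out = 257), power = rep(1, 257))
  shf <- spectral_shape(flat)
  expect_equal(shf$entropy, 1)
  expect_equal(shf$spectral_centroid, 2000)
  expect_equal(shf$q25_freq, 1000, tolerance = 2 * bin)
  expect_equal(shf$q50_freq, 2000, tolerance = 2 * bin)
  expect_equal(shf$q75_freq, 3000, tolerance = 2 * bin)
  expect_equal(shf$spectral_slope, 0, tolerance = 1e-9)

  two <- tone(500, 0.04) + tone(1500, 0.04)
  sh2 <- spectral_shape(frame_spectrum(two * blackman320(), rate))
  expect_lt(abs(sh2$spectral_centroid - 1000), bin)

  expect_error(spectral_shape(list(freqs = 1:5, power = rep(0, 5))),
               "zero spectrum")
})

test_that("LPC recovers planted formants within tolerance", {
  # single resonator at 500 Hz, bandwidth 80 Hz
  x <- synth_vowel(16000, 500, 80, seed = 3)
  fs <- frame_signal(audio_recording(x, rate, "float32"))
  f1 <- vapply(seq_len(nrow(fs$frames)), function(i)
    formants_lpc(fs$frames[i, ], rate)$f1_freq, numeric(1))
  expect_lt(abs(mean(f1, na.rm = TRUE) - 500), 25)

  # three-resonator synthetic vowel
  x3 <- synth_vowel(16000, c(500, 1500, 2500), c(80, 120, 160), seed = 2)
  fs3 <- frame_signal(audio_recording(x3, rate, "float32"))
  fm <- t(vapply(seq_len(nrow(fs3$frames)), function(i)
    unlist(formants_lpc(fs3$frames[i, ], rate)), numeric(6)))
  means <- colMeans(fm[, c(1, 3, 5)], na.rm = TRUE)
  expect_lt(max(abs(means - c(500, 1500, 2500))), 50)
  # bandwidths positive where present
  expect_true(all(fm[, c(2, 4, 6)] > 0, na.rm = TRUE))

  # a pure sine concentrates sharp poles at the tone: every reported
  # formant sits on the line, none elsewhere in the band
  fmt <- formants_lpc(tone(800, 0.04), rate)
  expect_lt(abs(fmt$f1_freq - 800), 30)
  fs_all <- c(fmt$f1_freq, fmt$f2_freq, fmt$f3_freq)
  expect_true(all(abs(fs_all[!is.na(fs_all)] - 800) < 40))
  expect_lt(fmt$f1_width, 50)
})

test_that("harmonicity: NHR limits and subharmonic depth monotonicity", {
  w <- blackman320()
  clean <- pulse_train(1280, 53)[641:960]        # ~151 Hz, noiseless
  h <- harmonicity(clean, rate)
  expect_lt(h$noise_to_harmonics, 0.3)
  expect_equal(h$f0, rate / 53, tolerance = 5)

  set.seed(4)
  hn <- harmonicity(rnorm(320), rate)
  expect_gt(hn$noise_to_harmonics, 2)

  # NHR increases with added noise level
  nhr <- vapply(c(0, 0.02, 0.06, 0.15), function(s)
    harmonicity(pulse_train(1280, 53, noise = s, seed = 5)[641:960],
                rate)$noise_to_harmonics, numeric(1))
  expect_true(all(diff(nhr) > 0))

  # period doubling raises subharmonic depth
  depths <- vapply(c(0.2, 0.45, 0.7), function(a)
    harmonicity(pulse_train(1280, 36, alt = a)[641:960] * w,
                rate)$subharmonic_depth, numeric(1))
  expect_true(all(diff(depths) >= 0))
  expect_gt(depths[3], 2)
})

test_that("loudness follows Stevens' power law in overall gain", {
  sp <- frame_spectrum(synth_vowel(320, c(500, 1500), c(80, 120)) *
                         blackman320(), rate)
  l1 <- loudness_sone(sp, rate)
  sp2 <- sp; sp2$power <- 2 * sp$power
  expect_equal(loudness_sone(sp2, rate) / l1, 2^0.3, tolerance = 1e-9)

  expect_equal(loudness_sone(list(freqs = sp$freqs,
                                  power = rep(0, 257)), rate), 0)

  # same-power tones at 1 and 3 kHz within a factor of 2
  t1 <- loudness_sone(frame_spectrum(tone(1000, 0.04) * blackman320(),
                                     rate), rate)
  t3 <- loudness_sone(frame_spectrum(tone(3000, 0.04) * blackman320(),
                                     rate), rate)
  expect_gt(t1, 0); expect_gt(t3, 0)
  expect_lt(max(t1, t3) / min(t1, t3), 2)
})

test_that("sequence features: flux, novelty and roughness behave", {
  w <- blackman320()
  spec_of <- function(fr) frame_spectrum(fr * w, rate)$power

  # identical repeated frames
  f <- tone(700, 0.04)
  pw <- do.call(rbind, replicate(8, list(spec_of(f))))
  raw <- do.call(rbind, replicate(8, list(f)))
  sq <- sequence_features(pw, raw, rate, 160)
  expect_true(all(sq$spectral_flux == 0))
  expect_lt(max(sq$spectral_novelty), 1e-9)

  # abrupt tone switch: novelty peaks at the boundary frame
  sig <- c(rep(tone(600, 0.04), 6), rep(tone(2200, 0.04), 6))
  fs <- frame_signal(audio_recording(sig, rate, "float32"))
  pw2 <- do.call(rbind, lapply(seq_len(nrow(fs$frames)), function(i)
    frame_spectrum(fs$frames[i, ], rate)$power))
  sq2 <- sequence_features(pw2, fs$raw, rate, fs$hop)
  expect_equal(which.max(sq2$spectral_novelty), 12, tolerance = 1)

  # amplitude modulation at 100 Hz raises roughness
  am <- (1 + 0.8 * sin(2 * pi * 100 * (0:(8000 - 1)) / rate)) *
    tone(1000, 1)
  fa <- frame_signal(audio_recording(am / max(abs(am)), rate, "float32"))
  fp <- frame_signal(audio_recording(tone(1000, 1), rate, "float32"))
  ra <- sequence_features(
    do.call(rbind, lapply(seq_len(nrow(fa$frames)), function(i)
      frame_spectrum(fa$frames[i, ], rate)$power)),
    fa$raw, rate, fa$hop)
  rp <- sequence_features(
    do.call(rbind, lapply(seq_len(nrow(fp$frames)), function(i)
      frame_spectrum(fp$frames[i, ], rate)$power)),
    fp$raw, rate, fp$hop)
  expect_gt(mean(ra$roughness), mean(rp$roughness) + 0.1)

  # single-frame segment gets zeros
  sq1 <- sequence_features(pw[1, , drop = FALSE], raw[1, , drop = FALSE],
                           rate, 160)
  expect_equal(unlist(sq1), c(spectral_flux = 0, spectral_novelty = 0,
                              roughness = 0))
})

test_that("extract_features builds the labeled frame table", {
  sig <- synth_vowel(16000, c(500, 1500, 2500), c(80, 120, 160), seed = 6)
  rec <- audio_recording(sig * 0.5, rate, "float32", "call1", "A", "male")
  ann <- tibble::tibble(segment_id = "s1", call_id = "call1",
                        start_s = 0.5, end_s = 1.5,
                        distress_rating = 7L,
                        distress_label = factor("high",
                                                levels = c("low", "high")))
  ft <- extract_features(rec, ann)
  expect_equal(nrow(ft), 49)                     # 1 s of 40 ms / 50% frames
  expect_true(all(ft$distress_label == "high"))  # label broadcast
  expect_true(all(ft$caller_id == "A"))
  expect_true(all(is.finite(as.matrix(ft[distress_features()]))))
  expect_true(all(ft$q25_freq <= ft$q50_freq &
                    ft$q50_freq <= ft$q75_freq))
  expect_true(all(ft$entropy >= 0 & ft$entropy <= 1))

  # fully silent segment: warning, zero rows
  rec0 <- audio_recording(rep(0, 16000), rate, "float32", "call1",
                          "A", "male")
  expect_warning(ft0 <- extract_features(rec0, ann), "silent")
  expect_equal(nrow(ft0), 0)

  # annotation outside the audio
  ann_bad <- dplyr::mutate(ann, end_s = 10)
  expect_error(extract_features(rec, ann_bad), "bounds")
})

test_that("features are polarity-invariant; only gain features track gain", {
  sig <- synth_vowel(16000, c(550, 1600), c(90, 130), seed = 8)
  ann <- tibble::tibble(segment_id = "s1", call_id = "c", start_s = 0.2,
                        end_s = 1.4, distress_rating = 2L,
                        distress_label = factor("low",
                                                levels = c("low", "high")))
  mk <- function(x) extract_features(
    audio_recording(x, rate, "float32", "c", "A", "female"), ann)

  a <- mk(sig * 0.5)
  b <- mk(-sig * 0.5)         # polarity flip
  expect_equal(as.data.frame(a[distress_features()]),
               as.data.frame(b[distress_features()]), tolerance = 1e-6)

  g <- mk(sig * 0.1)          # gain change (before pcm16 quantization)
  gain_feats <- c("rms_db", "loudness")
  shape_feats <- setdiff(distress_features(), gain_feats)
  expect_equal(as.data.frame(a[shape_feats]),
               as.data.frame(g[shape_feats]), tolerance = 0.05)
  expect_lt(mean(g$rms_db), mean(a$rms_db) - 10)
})
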