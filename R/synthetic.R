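#' Default planted feature-effect map
#'
#' The (feature, sex) effects the generator plants, with the signs the
#' distress--voice relationships are expected to take: louder male speech
#' (`rms_db` +), lowered male first formant (-), reduced subharmonic depth
#' in both sexes (-), and for female callers increased entropy, noise to
#' harmonics ratio, median frequency and (shallower) spectral slope (+).
#' `shape` is `"linear"` or `"quadratic"` (monotone with curvature, so the
#' selection model must find edf > 1).
#'
#' @param scale Multiplier on every effect magnitude (0 = null data).
#' @return Tibble: `feature`, `sex`, `size`, `shape`.
#' @export
default_effect_map <- function(scale = 1) {
  tibble::tibble(
    feature = c("rms_db", "f1_freq", "subharmonic_depth",
                "entropy", "noise_to_harmonics", "q50_freq",
                "spectral_slope", "subharmonic_depth"),
    sex = c("male", "male", "male",
            "female", "female", "female", "female", "female"),
    size = scale * c(0.8, -0.8, -0.7, 0.8, 0.7, 0.7, 0.7, -0.7),
    shape = c("linear", "quadratic", "linear",
              "quadratic", "linear", "linear", "linear", "linear"))
}

#' Synthetic-study configuration
#'
#' Defaults emulate the study design: 120 callers (87 female / 33 male),
#' a mean of 7.7 segments per call (SD ~4.2), distress-thermometer
#' ratings with mean 4.92 and SD 2.13 dichotomized at 4, caller-level
#' random intercepts, caller-specific voice baselines, within-segment
#' AR(1) feature noise, and the sex-moderated planted effects of
#' [default_effect_map()].
#'
#' @param n_callers Number of callers.
#' @param n_female Number of female callers (rest male).
#' @param segments_mean,segments_sd Per-call segment count distribution
#'   (negative binomial, min 1).
#' @param frames_meanlog,frames_sdlog Per-segment non-silent frame count
#'   (lognormal, min 5; defaults give ~100 frames/segment).
#' @param cutoff Dichotomization cutoff on the 0--10 rating.
#' @param high_prev Population probability that a segment is in the
#'   high-distress state (default 0.36, the study's segment class split).
#' @param rating_low_mean,rating_low_sd,rating_high_mean,rating_high_sd
#'   Latent rating distribution per state; ratings are the rounded,
#'   clipped latents, so the marginal rating distribution is bimodal.
#' @param caller_intercept_sd SD of the caller random intercept on the
#'   logit of the high-state probability (the level-2 random effect).
#' @param caller_feature_sd SD of caller voice-identity offsets
#'   (feature-SD units).
#' @param rho Within-segment AR(1) autocorrelation of feature noise.
#' @param noise_sd Stationary frame-noise SD (feature-SD units).
#' @param effect_map Tibble from [default_effect_map()].
#' @param silence_fraction Fraction of silence injected into synthesized
#'   audio.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_callers = 120, n_female = 87,
                       segments_mean = 7.7, segments_sd = 4.22,
                       frames_meanlog = log(100) - 0.18,
                       frames_sdlog = 0.6,
                       cutoff = 4, high_prev = 0.36,
                       rating_low_mean = 2, rating_low_sd = 1.2,
                       rating_high_mean = 7.6, rating_high_sd = 1.3,
                       caller_intercept_sd = 1.5, caller_feature_sd = 0.5,
                       rho = 0.6, noise_sd = 1,
                       effect_map = default_effect_map(),
                       silence_fraction = 0.3, seed = 1) {
  stopifnot(n_callers >= 2, n_female <= n_callers, rho >= 0, rho < 1,
            cutoff >= 0, cutoff <= 10, noise_sd > 0)
  structure(list(
    n_callers = n_callers, n_female = n_female,
    segments_mean = segments_mean, segments_sd = segments_sd,
    frames_meanlog = frames_meanlog, frames_sdlog = frames_sdlog,
    cutoff = cutoff, high_prev = high_prev,
    rating_low_mean = rating_low_mean, rating_low_sd = rating_low_sd,
    rating_high_mean = rating_high_mean, rating_high_sd = rating_high_sd,
    caller_intercept_sd = caller_intercept_sd,
    caller_feature_sd = caller_feature_sd, rho = rho,
    noise_sd = noise_sd, effect_map = effect_map,
    silence_fraction = silence_fraction, seed = seed
  ), class = "sim_config")
}

# plausible telephone-band feature baselines (natural units): mean and SD
feature_baselines <- function() {
  tibble::tribble(
    ~feature,             ~mean_male, ~mean_female, ~sd,
    "rms_db",                 -28,        -29,        4,
    "dominant_freq",          420,        480,       90,
    "entropy",               0.45,       0.42,      0.1,
    "f1_freq",                510,        555,       70,
    "f1_width",                90,         95,       25,
    "f2_freq",               1480,       1620,      150,
    "f2_width",               130,        140,       35,
    "f3_freq",               2480,       2720,      200,
    "f3_width",               170,        180,       45,
    "spectral_flux",         0.35,       0.36,      0.1,
    "noise_to_harmonics",     0.9,        0.8,      0.3,
    "loudness",               2.4,        2.3,      0.5,
    "spectral_novelty",       0.5,        0.5,     0.15,
    "peak_freq",              450,        510,      110,
    "q25_freq",               430,        470,       80,
    "q50_freq",               820,        900,      140,
    "q75_freq",              1900,       2050,      260,
    "roughness",             0.25,       0.26,     0.07,
    "spectral_centroid",     1150,       1250,      180,
    "spectral_slope",        -9.5,       -9.0,      1.8,
    "subharmonic_depth",      6.0,        5.5,      2.5)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Simulate a frame-level feature table with known ground truth
#'
#' Callers get a sex, a distress-propensity intercept and voice-identity
#' feature offsets; segments get a discretized latent rating (label =
#' rating >= cutoff); frames get feature values = sex baseline + caller
#' offset + planted distress effect + AR(1) noise. Fully reproducible
#' from `config$seed` (R's Mersenne-Twister stream).
#'
#' @param config A [sim_config()].
#' @return Tibble shaped like [extract_features()] output (caller_id,
#'   call_id, sex, segment_id, distress_rating, distress_label, time, 21
#'   features) with a `ground_truth` attribute: `callers` (intercepts),
#'   `effect_map`, per-frame `distress_z`.
#' @export
simulate_frames <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    bl <- feature_baselines()
    feats <- bl$feature
    n_c <- config$n_callers
    sexes <- c(rep("female", config$n_female),
               rep("male", n_c - config$n_female))
    callers <- tibble::tibble(
      caller_id = sprintf("C%03d", seq_len(n_c)),
      sex = sexes,
      intercept = stats::rnorm(n_c, 0, config$caller_intercept_sd))
    voice_off <- matrix(stats::rnorm(n_c * length(feats), 0,
                                     config$caller_feature_sd),
                        n_c, length(feats),
                        dimnames = list(callers$caller_id, feats))

    nb_size <- if (config$segments_sd^2 > config$segments_mean)
      config$segments_mean^2 / (config$segments_sd^2 - config$segments_mean)
    else Inf
    rows <- vector("list", n_c)
    for (ci in seq_len(n_c)) {
      n_seg <- if (is.finite(nb_size))
        max(1L, stats::rnbinom(1, size = nb_size, mu = config$segments_mean))
      else max(1L, stats::rpois(1, config$segments_mean))
      seg_list <- vector("list", n_seg)
      p_high <- stats::plogis(stats::qlogis(config$high_prev) +
                                callers$intercept[ci])
      for (si in seq_len(n_seg)) {
        state <- stats::rbinom(1, 1, p_high)
        latent <- if (state == 1)
          stats::rnorm(1, config$rating_high_mean, config$rating_high_sd)
        else stats::rnorm(1, config$rating_low_mean, config$rating_low_sd)
        rating <- as.integer(pmin(10, pmax(0, round(latent))))
        d <- (rating - config$cutoff + 0.5) / 3
        n_f <- max(1L, round(stats::rlnorm(1, config$frames_meanlog,
                                           config$frames_sdlog)))
        Z <- matrix(0, n_f, length(feats),
                    dimnames = list(NULL, feats))
        # AR(1) noise per feature, stationary sd = noise_sd
        e <- matrix(stats::rnorm(n_f * length(feats)), n_f)
        if (config$rho > 0 && n_f > 1) {
          for (t in 2:n_f)
            e[t, ] <- config$rho * e[t - 1, ] +
              sqrt(1 - config$rho^2) * e[t, ]
        }
        Z <- Z + config$noise_sd * e
        # planted effects for this sex
        em <- config$effect_map[config$effect_map$sex ==
                                  callers$sex[ci], , drop = FALSE]
        if (nrow(em)) for (k in seq_len(nrow(em))) {
          # saturating monotone response: distress shifts voice quality
          # toward a characteristic regime rather than without bound, so
          # dichotomized low/high material forms two frame clusters
          shift <- if (em$shape[k] == "quadratic")
            em$size[k] * (tanh(1.3 * d) + 0.35 * (d^2 - 1))
          else em$size[k] * 1.2 * tanh(1.3 * d)
          Z[, em$feature[k]] <- Z[, em$feature[k]] + shift
        }
        # caller voice identity
        Z <- sweep(Z, 2, voice_off[ci, ], `+`)
        seg_list[[si]] <- tibble::tibble(
          caller_id = callers$caller_id[ci],
          call_id = callers$caller_id[ci],
          sex = callers$sex[ci],
          segment_id = sprintf("%s_seg%02d", callers$caller_id[ci], si),
          distress_rating = rating,
          distress_label = factor(
            ifelse(rating >= config$cutoff, "high", "low"),
            levels = c("low", "high")),
          time = (seq_len(n_f) - 1) * 0.02,
          distress_z = d)
        mu_sex <- if (callers$sex[ci] == "male") bl$mean_male
                  else bl$mean_female
        vals <- sweep(sweep(Z, 2, bl$sd, `*`), 2, mu_sex, `+`)
        seg_list[[si]] <- dplyr::bind_cols(
          seg_list[[si]], tibble::as_tibble(vals))
      }
      rows[[ci]] <- dplyr::bind_rows(seg_list)
    }
    out <- dplyr::bind_rows(rows)
    gt <- list(callers = callers, effect_map = config$effect_map,
               distress_z = out$distress_z)
    out <- dplyr::select(out, -"distress_z")
    attr(out, "ground_truth") <- gt
    out
  })
}

# second-order resonator filter for one formant
resonate <- function(x, f, bw, rate) {
  r <- exp(-pi * bw / rate)
  th <- 2 * pi * f / rate
  a <- c(1, -2 * r * cos(th), r^2)
  gain <- sum(a)  # unity at DC-ish; keeps levels bounded
  as.numeric(signal::filter(signal::Arma(b = max(gain, 0.05), a = a), x))
}

#' Synthesize telephone-band call audio with planted distress effects
#'
#' Source-filter synthesis per segment: a glottal pulse train (sex-typical
#' f0, one-pole spectral tilt) through three formant resonators plus
#' aspiration noise, band-limited to 300--3400 Hz at 8 kHz. High distress
#' shifts the acoustics in the planted directions: males get more gain, a
#' lowered F1 and alternating-amplitude periods (subharmonics); females
#' get more aspiration noise, a shallower tilt, a raised median frequency
#' and alternating periods. Interleaved silence at the configured
#' fraction. Writes one WAV + Audacity label TSV per call and a metadata
#' CSV.
#'
#' @param config A [sim_config()] (use a small `n_callers` /
#'   `segments_mean`; audio synthesis at full study scale is slow).
#' @param dir Output directory (created if needed).
#' @param rate Sampling rate (default 8000).
#' @param segment_duration Range (s) of voiced segment durations.
#' @return Tibble metadata: `call_id`, `caller_id`, `sex`, `wav`,
#'   `labels`, with file paths; also written as `metadata.csv` in `dir`.
#' @export
synthesize_calls <- function(config = sim_config(n_callers = 8,
                                                 n_female = 5,
                                                 segments_mean = 3),
                             dir = tempfile("calls"), rate = 8000,
                             segment_duration = c(0.6, 1.1)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    n_c <- config$n_callers
    sexes <- c(rep("female", config$n_female),
               rep("male", n_c - config$n_female))
    intercepts <- stats::rnorm(n_c, 0, config$caller_intercept_sd)
    meta <- vector("list", n_c)
    for (ci in seq_len(n_c)) {
      sex <- sexes[ci]
      caller_id <- sprintf("C%03d", ci)
      f0_base <- if (sex == "male") stats::rnorm(1, 115, 8)
                 else stats::rnorm(1, 205, 12)
      fmt_base <- if (sex == "male") c(500, 1480, 2450)
                  else c(555, 1620, 2700)
      fmt_base <- fmt_base * stats::rnorm(3, 1, 0.03)
      n_seg <- max(2L, stats::rpois(1, config$segments_mean))
      sil_gap <- function() {
        g <- config$silence_fraction
        stats::runif(1, 0.15, 0.45) * (g / 0.3)
      }
      samples <- numeric(round(sil_gap() * rate))
      labels <- NULL
      p_high <- stats::plogis(stats::qlogis(config$high_prev) +
                                intercepts[ci])
      for (si in seq_len(n_seg)) {
        state <- stats::rbinom(1, 1, p_high)
        latent <- if (state == 1)
          stats::rnorm(1, config$rating_high_mean, config$rating_high_sd)
        else stats::rnorm(1, config$rating_low_mean, config$rating_low_sd)
        rating <- as.integer(pmin(10, pmax(0, round(latent))))
        high <- rating >= config$cutoff
        dur <- stats::runif(1, segment_duration[1], segment_duration[2])
        n <- round(dur * rate)

        f0 <- f0_base * stats::rnorm(1, 1, 0.02)
        fmt <- fmt_base * stats::rnorm(3, 1, 0.02)
        # segment-to-segment acoustic variability keeps the classes
        # overlapping: distress shifts voice quality on average, not
        # deterministically
        gain_db <- stats::rnorm(1, 0, 1.2)
        noise_gain <- stats::runif(1, 0.02, 0.04)
        tilt <- 0.96 + stats::rnorm(1, 0, 0.01)
        alt <- stats::runif(1, 0.02, 0.15)
        if (sex == "male" && high) {
          gain_db <- gain_db + stats::rnorm(1, 3.5, 1)
          fmt[1] <- fmt[1] * stats::rnorm(1, 0.88, 0.03)
          alt <- stats::runif(1, 0.25, 0.45)
        }
        if (sex == "female" && high) {
          noise_gain <- noise_gain + stats::runif(1, 0.02, 0.05)
          tilt <- 0.91 + stats::rnorm(1, 0, 0.015)
          fmt <- fmt * stats::rnorm(1, 1.04, 0.015)
          alt <- stats::runif(1, 0.15, 0.35)
        }
        period <- max(10L, round(rate / f0))
        pulses <- numeric(n)
        pos <- seq(1, n, by = period)
        amp <- rep(c(1, 1 - alt), length.out = length(pos))
        pulses[pos] <- amp
        # one-pole lowpass for glottal spectral tilt
        src <- as.numeric(signal::filter(
          signal::Arma(b = 1 - tilt, a = c(1, -tilt)), pulses))
        voiced <- src
        for (k in 1:3) voiced <- resonate(voiced, fmt[k],
                                          c(80, 120, 160)[k], rate)
        voiced <- voiced / max(1e-9, stats::sd(voiced)) * 0.12
        noise <- stats::rnorm(n, 0, noise_gain)
        noise <- resonate(noise, fmt[1], 300, rate)
        seg <- (voiced + noise) * 10^(gain_db / 20)
        # telephone band limit
        bf <- signal::butter(4, c(300, 3400) / (rate / 2), type = "pass")
        seg <- as.numeric(signal::filtfilt(bf, seg))
        start_s <- length(samples) / rate
        samples <- c(samples, seg, numeric(round(sil_gap() * rate)))
        labels <- rbind(labels,
                        data.frame(start = start_s,
                                   end = start_s + n / rate,
                                   label = rating))
      }
      samples <- samples / max(1, max(abs(samples)) / 0.9)
      rec <- audio_recording(samples, rate, "float32", caller_id,
                             caller_id, sex)
      wav <- file.path(dir, paste0(caller_id, ".wav"))
      lab <- file.path(dir, paste0(caller_id, "_labels.txt"))
      write_wav(rec, wav, "pcm16")
      utils::write.table(labels, lab, sep = "\t", row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
      meta[[ci]] <- tibble::tibble(call_id = caller_id,
                                   caller_id = caller_id, sex = sex,
                                   wav = wav, labels = lab)
    }
    md <- dplyr::bind_rows(meta)
    utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
    md
  })
}

#' Small deterministic fixtures for tests and examples
#'
#' * `tiny_features`: ~10 callers / ~40 segments / ~2,000 frames with the
#'   default planted effects.
#' * `null_features`: same shape, all effect magnitudes zero.
#' * `tiny_audio`: <= 20 s of synthesized audio over 8 callers (both
#'   sexes), written to `dir`.
#'
#' @param kind One of `"tiny_features"`, `"null_features"`,
#'   `"tiny_audio"`.
#' @param dir Output directory for `tiny_audio`.
#' @param seed Seed (default 0 gives the canonical fixture).
#' @return A frame tibble for the feature fixtures, or the metadata tibble
#'   of [synthesize_calls()] for `tiny_audio`.
#' @export
make_fixture <- function(kind = c("tiny_features", "null_features",
                                  "tiny_audio"),
                         dir = tempfile("fixture"), seed = 0) {
  kind <- match.arg(kind)
  switch(kind,
    tiny_features = simulate_frames(sim_config(
      n_callers = 10, n_female = 7, segments_mean = 4, segments_sd = 2,
      frames_meanlog = log(50), frames_sdlog = 0.4, seed = seed)),
    null_features = simulate_frames(sim_config(
      n_callers = 10, n_female = 7, segments_mean = 4, segments_sd = 2,
      frames_meanlog = log(50), frames_sdlog = 0.4,
      effect_map = default_effect_map(0), seed = seed)),
    tiny_audio = synthesize_calls(sim_config(
      n_callers = 12, n_female = 7, segments_mean = 2,
      silence_fraction = 0.12, seed = seed), dir = dir,
      segment_duration = c(0.37, 0.5)))
}
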