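# Shared fixtures, built once per test run and cached in an environment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# moderate signal-bearing frame table (the default study conditions at
# reduced size: 24 callers, ~2,500 frames)
signal_frames <- function(seed = 1) {
  cached(paste0("signal", seed), function() {
    simulate_frames(sim_config(
      n_callers = 24, n_female = 16, segments_mean = 5, segments_sd = 2,
      frames_meanlog = log(22), frames_sdlog = 0.4, seed = seed))
  })
}

planted_pairs <- function() {
  em <- default_effect_map()
  paste(em$feature, em$sex)
}

# a pure tone of given frequency/duration, full scale
tone <- function(freq, dur_s = 1, rate = 8000, amp = 1) {
  amp * sin(2 * pi * freq * (seq_len(dur_s * rate) - 1) / rate)
}

# white noise through the generator's formant resonators
synth_vowel <- function(n, formants, bws, rate = 8000, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  for (k in seq_along(formants))
    x <- voicedistress:::resonate(x, formants[k], bws[k], rate)
  x / max(abs(x))
}

# glottal-like pulse train with period-doubling alternation and noise
pulse_train <- function(n, period, alt = 0, tilt = 0.96, noise = 0,
                        seed = 1) {
  set.seed(seed)
  p <- numeric(n)
  pos <- seq(1, n, by = period)
  p[pos] <- rep(c(1, 1 - alt), length.out = length(pos))
  src <- as.numeric(signal::filter(signal::Arma(b = 1 - tilt,
                                                a = c(1, -tilt)), p))
  src + stats::rnorm(n, 0, noise)
}

blackman320 <- function() signal::blackman(320)
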