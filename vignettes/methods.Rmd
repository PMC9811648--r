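---
title: "Methods: frame-level distress classification for telephone speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frame-level distress classification for telephone speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voicedistress)
```

This vignette documents the models and numerical choices behind
`voicedistress`: what each stage assumes, which defaults matter and why,
what the synthetic generator does and does not emulate, and where the
design was genuinely open. It states no empirical result beyond what the
package's test suite and `scripts/acceptance.R` themselves compute.

## The problem and the data model

The unit of analysis is the 40-ms speech frame. Mono 8 kHz call audio is
annotated with variable-length segments, each carrying a
distress-thermometer rating (0–10) that is dichotomized at the clinical
cutoff of 4; the segment's binary label is broadcast to all of its
frames. Frames are therefore strongly dependent: the label is *constant*
within a segment, acoustic features are autocorrelated within a segment,
and both labels and voice characteristics cluster within callers. Most
of the statistical choices below exist to respect that dependence.

## Preprocessing and framing

Audio is quantized to the 16-bit PCM grid, mean-removed, and
pre-emphasized with `y[t] = x[t] − α·x[t−1]`, α = 0.97 (the standard
speech value; configurable). Segments are cut into 40-ms Blackman
frames with 50% overlap; trailing partial frames are discarded and frame
times are frame centers. A frame is silent when its raw RMS falls below
−50 dBFS (configurable); silent frames are excluded everywhere
downstream. Non-8 kHz input is accepted with a warning and analyzed over
`[0, rate/2]`.

## The feature set

Twenty-one per-frame variables are computed from a 512-point zero-padded
one-sided power spectrum (Parseval-scaled), over the 0–4 kHz band:

* `rms_db` on the raw (unwindowed) frame; `loudness` as Zwicker
  critical-band power mapped through Stevens' law (intensity^0.3).
  These are the only gain-dependent features.
* Spectral shape: power-weighted centroid, argmax peak, dominant
  frequency (lowest local peak reaching 10% of the maximum), cumulative
  quartile frequencies, least-squares dB-vs-kHz slope, and Wiener
  entropy (geometric/arithmetic mean of power, 0 = pure tone,
  1 = white noise).
* Formants F1–F3 by order-10 Burg LPC: pole angles give frequencies,
  pole radii give bandwidths; poles broader than 400 Hz are rejected as
  tilt-modeling artifacts, the first three survivors in
  (90, 3950) Hz are reported, missing ones are `NA`.
* Harmonicity from the normalized autocorrelation of the *raw* frame
  (the analysis window's taper biases long-lag correlation downward, so
  the windowed frame is not used here), searched over pitch periods
  75–300 Hz: `NHR = (1 − r*)/r*` clipped to [0, 10]. Subharmonic depth
  is the dB prominence of the strongest half-integer-harmonic peak over
  the inter-harmonic valley floor (medians of the two flanking valley
  bands, minimum of the two sides), over the first five harmonics. With
  40-ms frames the frequency resolution limits sensitivity at low f0;
  shallow period-doubling (alternation below roughly 0.2) is not
  detectable, which the tests acknowledge.
* Sequence context within a segment (never across): spectral flux
  between unit-normalized consecutive spectra, checkerboard-kernel
  novelty on a 5-frame cosine self-similarity window (edges replicated),
  and roughness as the 30–150 Hz fraction of the amplitude-envelope
  modulation spectrum over the same 5-frame span.

Telephone audio lacks the fundamental below the 300 Hz passband edge, so
no f0 feature is emitted; the pitch period used by the harmonicity
features is recoverable from harmonic spacing.

## Correlation screening

Greedy pruning at |Pearson r| ≥ 0.9: repeatedly find the worst pair and
drop the member with the larger mean absolute correlation to the other
survivors (ties alphabetically). Zero-variance columns are dropped
first. The procedure is deterministic and row-order invariant.

## The penalized GAMM

The selection model is a binomial GAMM on the logit scale: a global
intercept, a male-vs-female contrast, one centered cubic B-spline smooth
(9 basis functions, knots at within-sex quantiles of the z-scored
predictor) per (feature, sex), each carrying a second-difference penalty
plus a small identity shrinkage so the whole term can be penalized away,
and ridge-penalized caller intercepts. Fitting is penalized IRLS
(relative deviance tolerance 1e-8, 200 iterations).

Two numerical decisions deserve emphasis:

* **Smoothing selection.** Classical GCV degenerates on these data: the
  criterion decreases monotonically toward the least-smoothed end of the
  grid because within-segment label constancy lets wiggle absorb what
  looks like independent information. The default therefore selects the
  single shared smoothness multiplier and the caller ridge weight by
  *caller-grouped* cross-validated deviance over a log grid, predicting
  held-out callers with their random effect at zero. Near-ties (0.2%)
  resolve toward the stronger penalty, since the held-out criterion is
  nearly flat in the caller ridge weight. GCV remains available
  (`lambda_select = "gcv"`) and behaves on independent rows.
* **Term inference.** Model-based covariances are badly anti-conservative
  under frame clustering. Standard errors and tests use a caller-cluster
  robust covariance with a jackknife-type (CR3) leverage adjustment
  `(I − H_gg)^{-1}` per caller — without it the near-free caller
  intercepts absorb each caller's residual and deflate the sandwich —
  and the Wald statistic for a smooth is restricted to the leading
  rank-⌈edf⌉ eigenspace of its robust covariance block, referred to an F
  distribution with denominator df = (callers of that sex − 1). The
  published modeling account mentions "accounting for autocorrelation"
  without a mechanism; this cluster-robust construction is this
  package's realization of it, and its calibration is verified in the
  test suite against caller-bootstrap standard errors and null
  simulations.

One shared smoothing parameter cannot shrink individual null terms to
edf 0 while leaving signal terms unpenalized (that would require
per-term parameters); selection power comes from the robust tests, not
from per-term edf. Reported per-term `beta` is the slope of the fitted
smooth's linear projection onto the z-scored predictor — a standardized
log-odds-per-SD summary comparable across features.

Terms with p < α (default .05) are selected; if nothing is selected the
pipeline falls back to the full feature set with a warning.

## Clustering and principal components

k-means (k-means++ initialization, Lloyd iterations, best of 25 restarts
by within-cluster SS, deterministic given the seed, labels renumbered by
size) runs on the z-scored selected features. The elbow rule makes the
usual visual scree explicit: the chosen k is the smallest whose *next*
marginal explained-variance gain falls below 25% of the first gain; if
no gain ever does, the search is flagged as a weak elbow. Cramér's V
quantifies cluster–sex association; a binomial logistic regression of
2-cluster membership on the features reports McFadden pseudo-R² (with a
light ridge refit under perfect separation — note that clusters defined
by k-means in the same feature space are often perfectly separable, so
values near 1 are expected on clean synthetic data). The first two
principal components of the selected features (signs fixed so the
top-loading feature loads positively) are appended as predictors.

On the default synthetic conditions the per-sex effect profiles create
more than two frame groups (male-low/high, female-low/high), so the
elbow frequently lands at k = 3–4 rather than the k = 2 a single shared
distress axis would give; the planted-partition tests use explicit
two-blob data where k = 2 is the truth.

## Component-wise gradient boosting

Functional gradient descent on the binomial deviance from the log-odds
of the prevalence. Base learners: a P-spline per feature (9 B-spline
basis functions, second-difference penalty, ridge weight calibrated at
build time to ~4 effective df), a sex-difference P-spline per feature
(the decomposition makes moderation selectable per component), a ridge
learner over caller intercepts, an intercept learner, and one linear
learner per cluster PC. Each iteration fits every learner to the
negative gradient by penalized least squares and takes a ν = 0.1 step
along the best (smallest residual SS — the functional-gradient standard,
not 0/1 loss). The path records per-learner risk reductions, normalized
into variable importance.

The stopping iteration is chosen by caller-grouped, label-balanced
10-fold CV (folds never split a caller); leave-one-caller-out validation
then fits one model per caller and predicts the held-out caller with its
random effect at zero. Out-of-fold scores are pooled as deviations from
each training fold's base rate, re-anchored at the overall prevalence:
without this, the held-out caller's own labels shift its fold's offset
and, when the signal is weak, that nuisance *anti-ranks* the pooled
probabilities (the acceptance suite's leakage control would read ~0.15
instead of 0.5); with strong signal the adjustment is negligible.

Youden's J picks the operating threshold over observed cutpoints (ties
toward 0.5); AUROC uses midranks and AUPRC stepwise precision–recall
integration, with percentile bootstrap CIs resampling callers, not
frames. Segment decisions are mean frame probabilities against the same
frame-level threshold (the published description aggregates exactly so;
no separate segment threshold is fitted). Printed percentages round
half-up to 2 dp (frames) and 1 dp (segments).

## The synthetic generator

`simulate_frames()` emulates the study's design: 120 callers (87 female
/ 33 male) by default, negative-binomial segments per call (mean 7.7,
SD 4.2), lognormal frames per segment (~100), a two-state latent rating
mixture (low ~ N(2, 1.2²), high ~ N(7.6, 1.3²), rounded and clipped to
0–10) with the high-state probability at 0.36 — the published segment
class split — moved on the logit scale by a caller random intercept
(SD 1.5); caller voice-identity offsets (SD 0.5 feature-SD units) and
within-segment AR(1) noise (ρ = 0.6). The two-state mixture is used
because a unimodal rating distribution cannot simultaneously match the
published mean rating and the published class split; the class split is
the analysis-relevant quantity and wins.

Planted effects follow the published sign pattern (male: louder, lower
F1, shallower subharmonics; female: higher entropy, noise-to-harmonics,
median frequency and spectral slope, shallower subharmonics), as
saturating tanh responses in the standardized rating — distress moves a
voice toward a characteristic regime rather than without bound, which
also gives the dichotomized material its cluster structure. Effect
magnitudes (0.7–0.8 SD) are a one-time calibration to the intended
operating point of roughly 0.93 out-of-fold AUROC on the default
conditions: high but imperfect accuracy, so segment aggregation has
visible work to do. `synthesize_calls()` plants the same directions
acoustically (gain, F1 scaling, aspiration noise, spectral tilt,
alternating-amplitude pulses) in a glottal source–filter synthesis
band-limited to 300–3400 Hz, with per-segment acoustic variability so
classes overlap.

What the generator does *not* emulate: linguistic content, prosodic
dynamics beyond AR(1) noise, channel artifacts (codec, clipping, room),
counselor cross-talk, or rater disagreement. Passing tests therefore
demonstrate that the pipeline recovers the planted statistical structure
through the real DSP and modeling path — not that it would achieve any
particular accuracy on real helpline audio.

## Problem sizes used in the checks

The automated checks run the study design at reduced scale, chosen so
the full suite completes comfortably on a single CPU: selection-recovery
replicates use 24 callers and ~2,500 frames (25 replicates); null
calibrations use 20 callers with single-frame segments (the
independent-label regime); the leakage control uses 40 callers with
caller-dominated labels and zero planted effects; the end-to-end audio
fixture is ~19 s over 12 callers. `scripts/acceptance.R` re-runs the
pipeline at the 24-caller scale from a caller-supplied seed.

## Known limitations

* Exact numeric parity with any third-party feature extractor is out of
  scope; features carry explicit standard definitions instead.
* One shared smoothing parameter trades per-term adaptivity for speed;
  mgcv-style per-term selection would sharpen edf interpretation.
* Subharmonic depth is resolution-limited at telephone-band male f0.
* The published real-data results (AUROC 97.39%, the Table-style
  coefficient values, the 68/23.4/4.4/4.2 importance split) depend on
  confidential recordings and are not reproduction targets; the package
  reproduces the *printed confusion arithmetic* exactly and the
  qualitative behavior (selection, leakage protection, aggregation
  gains, cluster-PC contribution) on synthetic conditions.
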