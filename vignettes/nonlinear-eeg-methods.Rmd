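---
title: "Nonlinear EEG features and group statistics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear EEG features and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nleeg)
```

## Scope

`nleeg` implements a resting/stimulus EEG analysis chain built around five
time-domain and nonlinear features — Higuchi fractal dimension (FD),
Hilbert-envelope mean frequency in the wideband (EMF) and alpha (EMFA)
bands, the envelope coefficient of variation (RAT), and Hjorth mobility and
complexity — together with 1-Hz-binned spectral power, between-group and
stimulation-vs-rest statistics, and correlation maps between spectral power
and the nonlinear features and between subjective ratings and features.
Because clinical recordings of this kind are not publicly available, the
package ships a seeded synthetic-cohort generator that reproduces the
statistical structure such an analysis assumes, so every stage is testable
end to end.

This vignette documents the models, the tunable parameters and the
numerical design decisions; the statements made here are all checked by the
test suite or recomputed by `scripts/acceptance.R`.

## Preprocessing

All feature computation happens on band-limited signals:

| band      | default (Hz) | used for                               |
|-----------|--------------|----------------------------------------|
| wideband  | 1.6–30       | Hjorth parameters, EMF, RAT, PSD bins  |
| fd        | 2–20         | Higuchi fractal dimension              |
| alpha     | 8–13         | alpha envelope (EMFA)                  |

Filtering is a Butterworth band-pass of effective order 12, applied
zero-phase: a 6th-order design run forward and backward. Zero-phase
application is the default because FD and the Hjorth parameters are
waveform-shape statistics and a causal filter's group delay distorts
exactly the structure they measure; a causal single-pass mode remains
available (`filter$mode = "causal"`) for comparison with causal pipelines.

Two numerical choices matter here:

* **Second-order sections.** The filter is designed analytically
  (Butterworth prototype poles, lowpass-to-bandpass transform, bilinear
  transform, gain pinned to exactly 1 at the geometric center frequency)
  and applied as a cascade of biquads. A direct transfer-function
  realization of the same filter accumulates error at order 12 — on white
  noise the superposition residual reaches ~1e-4 in 2000 samples — while
  the cascade stays at machine precision (~1e-12), which is what lets the
  test suite assert linearity at 1e-9.
* **Odd-reflection padding.** Each series is extended by its point
  reflection about both endpoints (up to 2500 samples per side) before
  filtering, so start-up transients decay inside the padding. The padding
  is an affine, hence linearity-preserving, extension; with it a constant
  input maps to below 1e-6 of its amplitude everywhere, including the
  edges.

Artifact screening replaces manual editing with a deterministic rule: an
epoch is discarded iff any channel of the wideband-filtered epoch exceeds a
peak amplitude bound (default 100 µV, `artifact$threshold_uv`; `Inf`
disables screening). This is a reproducible stand-in, not a model of what a
human scorer does; it catches large transients only.

## The features

**Higuchi fractal dimension.** For lags `k = 1..k_max` and offsets
`m = 1..k`, the normalized length of the decimated series
`x[m], x[m+k], ...` is averaged into `L(k)`, and FD is minus the slope of
`ln L(k)` on `ln k`. FD is exactly 1 for a straight line and approaches 2
for uncorrelated noise; for fractional Brownian motion with Hurst exponent
H the theoretical value is `2 − H`, which is how the estimator is
validated (the package's own `gen_fbm()` uses exact circulant-embedding
covariances, an independent route). `k_max` defaults to 8: at 250 Hz with
multi-second epochs the estimate is stable for `k_max` anywhere in 6–16,
and 8 keeps the shortest usable epoch small (`10 × k_max` samples).

**Hjorth parameters.** Mobility is `sqrt(var(y′)/var(y))`, complexity
`mobility(y′)/mobility(y)`, with the derivative taken as the unscaled first
difference. The per-sample convention is deliberate: it keeps the
white-noise closed forms exact (`sqrt(2)` and `sqrt(3/2)`), and complexity
is invariant to the sampling-rate scale factor anyway. Mobility values
reported by this package are therefore in radians per sample; multiply by
`fs / 2π` for a hertz-scale reading. Both quantities equal their
periodogram spectral-moment forms (`sqrt(m2/m0)` and `sqrt(m4·m0)/m2` with
the difference-operator response `(2 sin(ω/2))^2`), which the tests verify
on tapered band-limited noise to 1%.

**Envelope features.** The amplitude envelope is the magnitude of the
analytic signal (FFT method). The first and last 0.5 s
(`features$trim_s`) are trimmed before any statistic, because the discrete
Hilbert transform is unreliable near the endpoints; with the trim the
envelope of a pure tone is constant to < 2% and an AM modulator is
recovered to < 3% RMS. Two statistics summarize envelope dynamics:

* *EMF / EMFA* — the amplitude-spectrum centroid of the mean-removed
  envelope over (0, 12] Hz. "Average frequency" of an envelope admits
  several formalizations; the centroid is the standard one, DC removal is
  mandatory (the envelope mean is large and carries no instability
  information), and the 12 Hz cap (`features$emf_cap_hz`) keeps the
  measure inside the physiologically meaningful amplitude-modulation
  range. A modal ("peak") variant is available via `features$emf_mode`.
  A near-constant envelope (CV below 1%) has no oscillation to summarize;
  EMF then returns 0 flagged degenerate rather than an arbitrary centroid
  of numerical noise.
* *RAT* — `sd(env)/mean(env)`. For sinusoidal AM of depth m this is
  `m/√2` exactly, which anchors the tests.

**PSD unit bins.** Power spectral density by Welch's method — Hann
windows, 50% overlap, density scaling — integrated by trapezoid over
[b, b+1) for b = 2..19 Hz. Adjacent bins share edge ordinates, so the
18-bin total equals the 2–20 Hz integral and Parseval's identity holds to
a few percent for band-limited signals. The segment length default is 4 s
(`features$welch_seg_s`): on the resulting 0.25 Hz grid the Hann main lobe
of a tonal component stays strictly inside one unit bin (a 10.5 Hz tone
puts > 95% of its power in the 10–11 Hz bin), whereas a 2 s segment
(0.5 Hz grid) unavoidably leaks one sixth of a half-bin-offset tone's
power onto each neighboring integer-frequency grid point, and no window
choice can put 95% of such a tone into one bin.

**Epoch handling.** Features are computed per presentation epoch and then
averaged within a condition, rather than computed once on the
concatenation: concatenating epochs creates phase discontinuities at the
joins that bias the Hilbert envelope, the FFT centroid and FD. Averaging
is idempotent (duplicated epochs change nothing) and permutation-invariant,
and both properties are tested.

## Statistics

The resting between-group contrast is a one-way ANOVA of the
subject-level feature value on group, per (feature, channel) — with five
groups this produces the `F(4, N−5)` statistics characteristic of this
design — followed by Tukey HSD post-hocs where the omnibus test survives
adjustment. The Bonferroni family defaults to the 19 channels within each
feature (`stats$family = "channels_within_feature"`), because results are
reported as per-feature channel lists ("all except ..."); a global
`all_cells` family is available. Setting `alpha = 1` is the documented
degenerate configuration in which every test is accepted.

Stimulation-vs-rest uses a paired t-test per (feature, channel) within a
group (Wilcoxon signed-rank below 8 pairs), with the sign convention
"+" = higher in rest, "−" = lower in rest.

Correlation maps are Pearson correlations with a two-level mask:
significance `p < alpha` and a display threshold `|r| > 0.35`
(`stats$r_display`). Non-significant cells keep their r but are flagged,
and constant inputs are flagged not-computable instead of producing an
undefined coefficient. The default unit of observation is the
(subject, condition) cell mean averaged over channels
(`stats$pooling = "channel_mean"`); per-channel pooling is available. The
channel-averaged default was chosen because the feature–power relations of
interest are global spectral effects, and channel-level pooling inflates n
with strongly dependent observations.

## The synthetic cohort

Each simulated channel is the sum of

1. **1/f background** — Gaussian noise spectrally shaped to
   `1/f^exponent` (flat below 1 Hz), unit variance, scaled by `base_uv`;
2. **band boosts** — band-pass-filtered noise adding `gain` times the
   background's analytic in-band power;
3. **a coherent rhythmic component** — an amplitude-modulated sinusoid
   shared across channels, with posterior-dominant weights (the
   physiological alpha topography) or uniform weights (the widespread
   rhythmic slow activity of severe brain injury).

Subject-level lognormal multipliers (`subject_sd`) on the background,
rhythm amplitude and band gains provide between-subject variance; the
underlying standard-normal factors are retained as the subject's latent
factors, and ratings are clamped Gaussians on each scale's range whose
standardized part is `rho·z + sqrt(1−rho²)·ε` against a chosen latent
factor, so rating–feature couplings hold in expectation. Comatose
subjects give no ratings, by design. Generation is fully seeded: a
cohort spec including its seed reproduces byte-identical files.

The default group profiles encode the qualitative resting contrasts the
analysis is meant to recover: slow-wave excess in coma, 5–9 Hz excess
after stroke, posterior alpha strongest in controls and slightly weaker in
mTBI, faster alpha modulation and stronger beta in schizophrenia. The
paper-style effect *magnitudes* are unknowable from published group
statistics, so the defaults were calibrated once — on the generator and
extractor alone — to make the contrasts detectable at 15 subjects per
group, and then frozen.

One calibration finding is worth recording because it is physics, not
tuning: adding broadband 2–7 Hz noise to a flat-ish 1/f background
*raises* Hjorth complexity (the spectral spread widens, and the
background's 20–30 Hz tail dominates the 4th spectral moment), which is
the opposite of the low complexity seen in comatose EEG. Reproducing the
comatose signature requires what real comatose EEG actually shows:
background slowing (the coma profile uses a 1/f exponent of 3) together
with a dominant, quasi-rhythmic slow excess. With those profiles the low
EMF / low mobility / low complexity / high RAT pattern, and the
correlation signs between band power and features (negative FD and Hjorth
vs slow power, positive vs beta power, positive RAT vs slow power),
emerge from the feature definitions rather than being injected directly.

What the generator does **not** emulate: ocular/muscle artifacts, evoked
response morphology, channel covariance beyond the single shared rhythm,
non-stationarity across the session, or biophysically realistic field
propagation. Passing tests therefore demonstrate that the analysis chain
recovers known structure of this statistical form — not that it is robust
to every property of clinical recordings.

## Problem sizes and determinism

The default testing cohort is five groups × 15 subjects, 19 channels,
four 10 s eyes-closed epochs per subject — a desk-scale stand-in for the
study design it emulates (2-minute rests, 30 s stimuli presented 8 times).
The statistical calibration check runs 1000 null repetitions at the
feature-table level (i.i.d. Gaussian subject values), which is the stage
the calibration claim concerns; a full EEG re-extraction per repetition
would add nothing to the type-I-error question. Rating-coupling recovery
uses 200 replicate single-channel cohorts of 30 subjects.

All randomness flows from explicit integer seeds (per-subject streams are
derived deterministically from the cohort seed), outputs carry a manifest
with the config hash, package version and per-file checksums, and the
pipeline tests assert byte-identical reruns.

## Known limitations

* EDF support covers the plain EDF/EDF+ layout with uniform sampling
  rates across selected channels; BDF and annotation decoding are out of
  scope.
* The mobility scale is per-sample (see above); cross-implementation
  comparisons must normalize conventions.
* The EMF centroid is one reasonable formalization of "average envelope
  frequency"; absolute EMF values are convention-dependent even though
  contrasts and correlations are stable across conventions.
* Bonferroni is the only multiplicity correction offered, matching the
  analysis this package reproduces; FDR-style alternatives are out of
  scope.
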