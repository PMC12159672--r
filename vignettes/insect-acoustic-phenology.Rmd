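---
title: "Inferring insect acoustic phenology from passive acoustic monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring insect acoustic phenology from passive acoustic monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tropical insect biophony — crickets, katydids and cicadas calling mostly
between 3 and 10 kHz — dominates forest soundscapes, yet insect activity is
rarely monitored at fine temporal scales. Passive acoustic monitoring (PAM)
produces recordings at a scale no annotator can label exhaustively: a
three-site, two-year deployment recording one minute in every ten plans
315,360 one-minute files. `phenoacoustics` implements a calibration
pipeline for that setting: a handful of acoustic indices summarize every
recording cheaply; a modest manually labelled subset calibrates those
indices against real insect activity; cyclic smooths interpolate the index
cycles across gaps; and a chained Monte Carlo step carries the uncertainty
of both models into the final activity estimates.

The package also ships a synthetic-soundscape generator, so the entire
chain — from waveform synthesis to propagated phenology — can be validated
against known ground truth without any field data.

## Pipeline stages and their models

### Acoustic indices (3–10 kHz)

Five per-clip indices are computed on a short-time Fourier transform
(Hann window, 512 samples, no overlap — the classical defaults of the R
ecoacoustics ecosystem, exposed as configuration):

* **ACI** (acoustic complexity): for each frequency bin and 5 s temporal
  chunk, the sum of absolute successive-frame amplitude differences divided
  by the chunk's total amplitude, summed over bins and chunks. Sensitive to
  amplitude modulation, invariant to uniform gain.
* **ADI** (acoustic diversity): Shannon entropy (natural log) of per-1 kHz
  band occupancy — the fraction of spectrogram cells above a −50 dB
  threshold relative to the clip's loudest cell. The clip is band-pass
  filtered to 3–10 kHz *first*, which empties the 0–3 kHz bands and
  deflates ADI; that ordering is deliberate — it is how the index is
  conventionally computed in band-limited insect work, filter first, band
  entropy second.
* **BI** (bioacoustic index): area of the band-limited mean dB spectrum
  above its quietest bin, in dB·kHz. Translation-invariant in dB.
* **H** (acoustic entropy): product of normalized spectral entropy (mean
  spectrum as a PMF) and normalized temporal entropy (Hilbert amplitude
  envelope as a PMF), in [0, 1]; computed on the band-passed clip.
* **NP**: count of mean-spectrum local maxima with prominence above 1% of
  the spectrum maximum, counted strictly inside 3–10 kHz after discarding
  frequencies below 300 Hz. Both the low cut and the prominence threshold
  are configuration: peak-counting recipes in the field rarely pin down a
  threshold, so the default here (1% prominence) is a documented choice.

Indices are min–max scaled to [0.0001, 0.9999] over the post-QC table (the
fitting set); the (min, max) pairs are persisted so new data can be scaled
identically. Scaling on post-QC rather than all clips is a documented
choice — the alternative is one flag away in the code.

### Quality control

Heavy rain is flagged by a two-band classifier: mean band power and band
signal-to-noise ratio (temporal mean / temporal SD of band amplitude) in
0.6–1.2 kHz and 4.4–5.6 kHz. Thresholds are the per-metric minima over
training rain clips shrunk by a safety factor (0.9), and a clip is flagged
only when all four metrics exceed their thresholds — rain is loud *and*
steady in both bands, while insect choruses are spectrally localized and
temporally structured. This is a deliberately simple two-band design in
the spirit of threshold-trained rain screens used in PAM workflows, not a
re-implementation of any existing tool's internals.

Recorder faults are caught by a squared Mahalanobis distance on the raw
five-index vector, computed from the full table's mean and covariance —
deliberately including the outliers themselves, so the screen is a plain
distance-from-the-bulk rule rather than a robust estimator with its own
tuning. Clips with squared distance over 12 are dropped; the threshold is
a squared distance (the convention of `stats::mahalanobis`) and is
configurable. Since
Mahalanobis distances are invariant to affine per-column rescaling, the
screen behaves identically on raw and scaled indices.

### Calibration models

Manual labels exist in two forms: *spectrogram coverage* (fraction of the
3–10 kHz × 15 s spectrogram window occupied by insect sound, quantized to
5%) and *sonotypes per 15 s* (count of distinct insect sound types).
Coverage is modelled with a beta distribution and logit link (after the
standard boundary squeeze `(y(n-1)+0.5)/n`, since 0 and 1 are legal manual
labels but outside the beta support); counts with Poisson and log link.

The candidate terms are the five scaled indices as linear and quadratic
terms plus site and year factors (12 toggles; quadratics may enter without
their linear term, since inclusion is counted per term). All 4096 subsets
are fitted and ranked by AICc; models within ΔAICc < 2 of the best are
averaged with Akaike weights using full (zero-substitution) averaging. The
averaged coefficient covariance adds the between-model spread to the
weighted within-model covariances, so prediction intervals reflect model
selection uncertainty. Cross-validation (5-fold, 100 repeats, unstratified)
evaluates the single best model on the response scale with RMSE and MAE.

The beta likelihood is maximized by Fisher scoring with step-halving on
the analytic score and expected information, with a bounded quasi-Newton
fallback; `log(phi)` is bounded above (at 16) so that degenerate,
effectively noiseless responses remain well-posed. The Poisson path is a
lean IRLS. Both are verified in the test suite against independent density
evaluations and a generic optimizer, and the Poisson fit against
`stats::glm`.

Workflows of this kind are often described as mixed models, but with
site and year as the only grouping variables — two or three levels each —
random effects buy nothing over fixed ones; the models here are
fixed-effects GLMs, with year a two-level factor.

### Cyclic smooths over the daily and annual cycles

Each scaled index is smoothed over hour (period 24) and day of year
(period 365) with cyclic cubic regression splines, four basis functions
each, plus a site × year interaction with sum-to-zero contrasts; Gaussian
errors. Fitting is delegated to `mgcv` — the standard engine for exactly
these smooths — with smoothness chosen by GCV, `mgcv`'s classical default
for Gaussian models. Four basis functions are deliberately few: the
smooths should capture broad diel and seasonal trends, not day-to-day
detail. The knot ranges are pinned to the full cycles (0–24, 0–365) so the
fitted smooths and their derivatives match across the wrap; the study
years are non-leap, so day-of-year is 1–365 with no ambiguity.

Whether "four basis functions" counts before or after the cyclic
identifiability constraint is ambiguous in the source description; `k = 4`
pre-constraint is used (three free columns after absorption), and `k` is a
configuration knob.

### Uncertainty propagation

For every grid point (hour × day-of-year × site × year), 1000 iterations
of a three-step chain:

1. draw each of the five index values independently from
   Normal(GAM mean, GAM se), clamped to the scaled support
   [0.0001, 0.9999];
2. build the calibration covariates from the drawn values (quadratics are
   squared after drawing — they are deterministic transforms, not
   independent draws) and evaluate the averaged model's mean and
   delta-method standard error;
3. draw activity from Normal(mean, se) on the response scale, clamped to
   the response support ([0, 1] for coverage, ≥ 0 for counts).

The five index draws are independent and the activity draw is taken on
the response scale; a joint draw across indices and a link-scale draw are
defensible alternatives (and the codebase keeps the hooks for them), but
the simple literal chain is the default. Clamp counts are recorded so
truncation is visible.
Summaries are the per-grid-point median, mean and central 95% interval
(type-7 quantiles).

## The synthetic soundscape generator

The generator emulates the statistical structure the analysis relies on,
not the perceptual quality of rainforest audio:

* **Sonotypes**: stylized call classes confined to 3–10 kHz — pulsed
  narrowband noise (cricket-like trills), pulsed broadband bursts
  (katydid/cicada-like) and sustained tones — with per-template centre
  frequency, bandwidth, pulse rate, duty cycle and peak level. The default
  library spans 3.7–9.3 kHz at levels −32 to −18 dBFS over a −60 dBFS
  noise floor.
* **Activity**: each sonotype is active in a clip independently with
  probability `plogis(baseline + a_h cos(2π(hour−p_h)/24) +
  a_d cos(2π(doy−p_d)/365))`. Defaults place peaks between 21.00 and 01.00
  and in August–October (the dry season at the emulated sites), with
  logit-scale amplitudes 2 (diel) and 1 (seasonal) — strong nocturnal
  cycling with a clear but weaker seasonal cycle, the qualitative regime
  the field data show.
* **Ground truth**: coverage is the fraction of spectrogram cells
  (3–10 kHz, first 15 s) where the clean insect signal exceeds the
  realized background by 6 dB, rounded to the nearest 0.05 — a computable
  analogue of a "nearest 5%" visual estimate. A sonotype is counted
  audible when it is active, its level clears the noise floor by the same
  margin, and it sounds for at least 1 s of the window.
* **Contamination**: rain clips receive low-frequency-weighted broadband
  noise; fault clips are near-silent or a stuck tone; a configurable
  fraction of planned files is simply missing. Mixtures that would clip
  are rescaled to −1 dBFS with a warning (configurable to error).

What the generator does *not* model: annotator confusion between
overlapping sonotypes (template identity is taken as truth), bird or
anuran biophony, wind, lunar effects, species-specific call structure.
Passing tests therefore demonstrate that the pipeline recovers known
structure under its own assumptions — not that acoustic indices are
reliable proxies in any particular real soundscape, which is exactly why
the calibration-against-manual-labels step exists.

## Desk-scale study sizes

The full deployment design (3 sites × 730 days × 144 clips/day × 60 s at
44.1 kHz) is the generator's default and remains available. The shipped
tests and the acceptance script run a thinned design chosen to keep a
complete run on a single CPU short while preserving both cycles: 2–3
sites, both study years thinned to every 24th day, 12 clips/day, 5 s clips
at 22.05 kHz (the Nyquist floor for a 10 kHz band with headroom), with
rain at 8% and faults at 5%. Monte Carlo sizes in the shipped runs are
1000 iterations (400 in the heaviest in-suite block) over a 24-hour ×
12-day grid. The in-suite end-to-end block uses the sonotype (Poisson)
response, whose all-subsets enumeration is much cheaper than the beta
response's; the acceptance script runs both responses.

## Numerical choices and degenerate inputs

* Silent clips yield flagged, NA index rows and are excluded before
  scaling rather than imputed.
* A constant index column makes min–max scaling degenerate and is an
  error, as is a singular index covariance in the Mahalanobis screen (the
  error names the near-collinear columns).
* AICc ties are broken by fewer terms, then lexicographic term labels, so
  rankings are deterministic.
* Submodels that fail to fit inside the enumeration are retried from a
  cold start, then excluded with a warning count.
* Cross-validation folds that lack a factor level seen in training skip
  those test rows with a warning.
* One global seed derives per-stage and per-clip seeds by string hashing,
  so any stage or clip can be regenerated in isolation, bit-identically.

## Known limitations

The calibration transfers only as far as the index–activity relationship
is stable; the rain classifier is a simplified two-band design and will
miss light rain (by design — light rain was an "intermediate" manual
label, handled by the distance screen); the Mahalanobis screen assumes
roughly elliptical index scatter and flags ~3.5% of clean clips at the
χ²₅ tail; and model-averaged intervals treat the five index draws as
independent, which understates joint uncertainty when indices are strongly
correlated.
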