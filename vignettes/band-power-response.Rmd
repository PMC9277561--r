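---
title: "Band-power biomarkers of treatment response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power biomarkers of treatment response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegresponse)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, what the synthetic-cohort
generator does and does not emulate, and the numerical and design choices
made where more than one defensible option existed. It states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis in one page

The package operationalizes a two-arm pre/post resting-EEG study design:

* **Labeling.** Patients are *responders* when both the clinical severity
  total (Sev) and the symptom count (Sx) improved strictly more than 50%:
  `(pre − post)/pre > 0.5` for both scores (`labelResponders()`). The
  strictly-greater reading means a patient at exactly 50% is a
  non-responder. Requiring *both* scores is a deliberate conjunctive
  reading of an ambiguous clinical rule; `bothScores = FALSE` switches to
  Sev alone. Subjects with a zero pre score have an undefined improvement
  fraction and are excluded with a warning rather than guessed at.
* **Signal conditioning** (`preprocessRecording()`), in fixed order:
  common-average re-reference → per-channel baseline (temporal mean)
  removal → zero-phase Butterworth band-pass (defaults 1–50 Hz, order 4)
  → fixed-length segment. Each step is pure (inputs are never mutated)
  and appends itself to the recording's provenance, so the applied chain
  is always recoverable from the object.
* **Spectral features** (`welchPsd()`, `bandPower()`): Welch PSD with 1 s
  Hamming-tapered segments at 50% overlap, one-sided density
  normalization (integrated PSD equals the variance of a demeaned
  signal); band power is the *mean* density over in-band bins.
* **Group statistics** (`changeRate()`, `compareGroups()`): change rate
  `(P_pre − P_post)/P_pre` per subject × channel × band (positive =
  power decreased after treatment), compared between groups channel-wise
  with a gated test choice and per-band Benjamini–Hochberg correction.
* **Prediction** (`crossValidatedSvm()`, `forwardChannelSelection()`,
  `svmPermutationTest()`): responder status predicted from *pre-treatment*
  band powers only, with a stratified 5-fold RBF-SVM, inner grid search,
  pooled-score ROC/AUC, greedy channel selection and a label-permutation
  test.

## 2. Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| band edges | 1–4, 4–8, 8–10, 10–12, 12–30 | Hz | canonical delta/theta/low-alpha/high-alpha/beta partition of resting EEG |
| band-pass cutoffs | 1, 50 | Hz | retains all analysis bands, removes drift and mains |
| filter order | 4 | – | common EEG practice; applied forward–backward, so the effective magnitude response is the square |
| Welch segment | 1 | s | 1 Hz resolution, 299 averaged periodograms over 150 s |
| Welch overlap | 0.5 | – | standard variance/efficiency compromise for Hamming tapers |
| responder threshold | 0.5 | fraction | the >50%-improvement rule |
| gate level α | 0.05 | – | normality and variance gates, and the FDR level reported |
| C, γ grids | 10^(−3..2) | – | logarithmic decades spanning 0.001–100 |
| outer / inner folds | 5 / 3 | – | 5-fold keeps ≥3 responders per fold at n = 17; 3 inner folds keep ≥4 per class in the grid search |
| n_perm | 1000 | – | permutation floor p = 1/1001 |

## 3. The synthetic cohort generator

`syntheticConfig()` defaults encode the emulated study conditions: 17
responders + 31 non-responders, a 62-channel extended 10-20 montage,
1000 Hz sampling, 150 s eyes-closed recordings.

**Signal model.** Each channel is a sum of independent band-limited
Gaussian noise components (one per band) plus a 1/f background — the
minimal stationary model in which per-band power is directly
controllable. Components are synthesized in the frequency domain (iid
complex-Gaussian Fourier coefficients on in-band bins), i.e.
white noise passed through an ideal band-pass filter.

**Calibration.** The Welch estimator smooths the true spectrum with the
squared window transfer function, so a flat band synthesized at level `s`
does not *measure* back at `s`: edge bins leak power into neighbouring
bands, and a 3-bin band like delta can read ~15% low while its neighbours
read high. The generator therefore solves a small linear system
`A s = target`, where `A[i, j]` is the expected measured mean PSD in band
i per unit synthesized PSD in band j, computed from the Hamming window's
power transfer at the configured segment length. The test suite checks
the resulting calibration to 5% (`test-synthetic.R`); in practice it is
accurate to ~2%. The calibration assumes the package's own measurement
convention (1 s Hamming segments, 50% overlap).

**Variability.** A lognormal factor with mean 1 on the power scale
(`subjectSd`, default 0.25 log-units) is drawn per subject × session ×
band. Because pre and post draws are independent, change rates acquire a
realistic spread (≈ 0.25·√2 ≈ 0.35) comparable to published cohort SDs,
rather than being determined by the effect map alone.

**Effects.** `defaultEffectMap()` encodes: responders' theta/beta power
falls after treatment (×0.72, ×0.69) while non-responders' rises (×1.08,
×1.10) — the beta factors reproduce the ~31% decrease / ~10% increase
reported for fronto-central sites in treated cohorts; and responders
carry ×1.35 delta power at CZ, O1, FC2, FC1 and F2 in *both* sessions.
The latter is the pre-treatment classification signal; applying it to
both sessions keeps delta change rates null, so the change-rate
statistics and the classifier are driven by different planted structure,
as in the emulated study design (significant theta/beta change-rate
differences without significant baseline differences). Effect-map rows
multiply, and `"*"` wildcards match any group/session/channel/band.

**Clinical scores.** Pre-treatment Sev is drawn on a 25–80 scale (group
means 42.8 / 37.4), Sx on 6–20; post scores are
`round(pre × (1 − improvement))` with improvement drawn around 0.77
(responders) or 0.19 (non-responders) and clamped so the record always
satisfies its group's strict responder rule even after integer rounding.
Subscale scores are not generated; only the totals drive labeling.

**Reproducibility.** One master seed; per-subject substreams are derived
by counter with L'Ecuyer-CMRG streams (responders and non-responders use
disjoint counter ranges), so enlarging one group never reshuffles
subjects already generated.

**What the generator does not emulate** — and hence what passing tests do
*not* demonstrate about real data: eye-blink/muscle artifacts (artifact
rejection is out of scope, so none are injected), non-stationarity,
inter-channel correlation (channels are independent, which makes
common-average re-referencing nearly a no-op rather than a genuine
spatial transform), oscillatory peaks (spectra are piecewise flat plus
1/f), and volume-conduction topography. Tests on this generator validate
the *estimators and inference machinery*, not the clinical effect sizes.

## 4. Numerical choices

* **Band edges are half-open** `[f_low, f_high)` on the discrete grid, so
  shared edges (4, 8, 10, 12 Hz) are never double-counted and beta
  excludes 30 Hz. "Band power" is the mean in-band density, which matches
  the sub-unit magnitudes typically reported for fronto-central beta;
  `mode = "integral"` gives total in-band power instead.
* **Welch normalization** is one-sided density with window-power
  compensation; Parseval consistency (integral ≈ variance, 3%) is
  enforced by test. No per-segment detrending beyond the global baseline
  removal already in the chain.
* **Test gating**: Lilliefors-corrected KS (normality is *estimated*
  mean/SD, so the plain KS null would be wrong); groups smaller than 5 or
  with zero variance count as non-normal and fall through to
  Mann–Whitney, which is computed with the normal approximation and tie
  correction. Levene uses mean centering. Welch–Satterthwaite fractional
  df when variances differ. Channels whose pooled values are constant are
  degenerate: excluded from testing and from the BH family, and reported
  as such.
* **FDR family** is the channels of one band (62 tests), not all
  channel × band tests; with five bands this is the more conservative
  reading per band and keeps bands interpretable in isolation.
* **Classifier determinism**: fold assignment, inner-CV folds, and
  permutations all derive from explicit seeds; grid-search ties break to
  the smallest C then smallest γ; forward-selection ties break to the
  earliest channel in montage order; the earliest AUC-maximizing prefix
  is the selected subset. The fold assignment is held fixed across the
  tentative evaluations of one selection run so comparisons are paired.
* **Decision-score orientation** is normalized so larger means more
  responder-like regardless of class ordering in the underlying SVM
  library; sensitivity refers to responders (the minority class) at
  decision threshold 0.

## 5. Design decisions where the design was open

* **Nested cross-validation only.** A flatter scheme — grid search on the
  full data followed by cross-validation with the chosen parameters —
  leaks test information into model selection and overstates performance.
  This package deliberately does not offer that mode: standardization
  statistics and hyperparameters are computed from training folds only,
  and the API provides no hook by which test-fold labels can reach
  fitting. A canary test verifies that a feature equal to the label is
  learnable (AUC ≈ 1) while a duplicated feature changes nothing.
* **Pooled-score ROC.** Held-out decision scores from all folds form one
  ROC. At n = 48, five per-fold ROCs built from 9–10 subjects each are
  too unstable to average meaningfully; pooling is the lower-variance
  choice. (Fold-wise score scales can differ slightly; with standardized
  features and a common threshold of 0 this effect is minor.)
* **Permutation test of the best model** is a plain label permutation
  with the add-one p-value `(1 + #{null ≥ obs})/(n_perm + 1)` — always a
  valid p-value, with floor 1/(n_perm+1). The full pipeline (fold
  assignment and inner grid search) is re-run on every permutation, so
  the null distribution reflects the entire selection-free fitting
  procedure. Note the channel *subset* is fixed before permuting; the
  p-value certifies the best model found, not a selection-corrected
  family-wise claim across all subsets.
* **Forward selection re-runs the grid search at every tentative
  addition** — costlier than fixing hyperparameters once, but the model
  for k channels should not inherit parameters tuned for k−1.

## 6. Problem sizes used by the test and acceptance suites

The statistical validation runs at reduced acquisition scale, chosen so
the full suite completes in minutes while keeping every replicate count
at its nominal value: null-cohort false-discovery checks use 200
replicate cohorts of 17 + 31 subjects, 6 channels, 128 Hz, 4 s; planted
change-rate shifts use 100 replicates at the full 62-channel layout;
channel-selection recovery uses 30 cohorts × 62 channels × 48 subjects
with single-point or 2×2 hyperparameter grids; permutation calibration
uses 200 replicates at n_perm = 99 (and the floor check n_perm = 199).
Spectral accuracy is tested at full acquisition scale (1000 Hz, 150 s).
`scripts/acceptance.R` documents the sizes it uses in its output (`n`
fields).

## 7. Known limitations

* Welch band powers assume stationarity over the analysis segment; no
  artifact handling is provided (by design).
* The EDF container is not read or written; recordings travel as plain
  CSV matrices with JSON sidecars. Converting EDF to this format is a
  one-liner in most EEG toolchains.
* `generateCohort()` at the full default scale (62 × 150 000 samples × 96
  recordings) occupies ~7 GB if recordings are kept; use the
  `perRecording` streaming callback (as `runPipeline()` and
  `writeCohort()` do).
* A full 62-step forward selection with the complete 6 × 6 grid and 1000
  permutations — the published analysis protocol — is computationally
  expensive (hours, not minutes); `maxSelectionSteps`, the grids and
  `nPerm` exist to scale studies to the time available.
* Between-channel independence in the generator means spatial statistics
  (e.g. the effect of common-average re-referencing on topography) are
  not meaningfully exercised.
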