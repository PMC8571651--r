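---
title: "Peak-fitting dimensional reduction for Raman tissue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-fitting dimensional reduction for Raman tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ramanpeaks)
```

## The problem

Confocal Raman micro-spectroscopy measures, for each tissue spot, a vector of
scattered-light intensities over Raman shifts of roughly 602–1726 cm⁻¹. Tissue
classes (for instance benign epithelium versus invasive carcinoma, or invasive
carcinoma versus intraductal carcinoma of the prostate) differ in the heights,
widths and positions of the vibrational bands riding on a large fluorescence
background. The standard machine-learning treatment feeds selected per-band
intensities ("intensity features") to a classifier. This package additionally
implements a model-based dimensional reduction: every consensus Raman peak is
fitted with a Gaussian, and the fitted amplitude (height) and standard
deviation (width, σ, in cm⁻¹) become features. The two feature families are
selected independently with L1-regularized linear SVMs and combined in a
radial-basis-function SVM.

## Preprocessing model and its assumptions

Raw acquisitions are handled in the order: accumulation summing, cosmic-ray
removal, rolling-ball baseline subtraction, standard normal variate (SNV)
normalization, and per-core averaging (`preprocess_cohort()`), followed by a
dataset-wide positivity shift before any Gaussian is fitted.

* **Cosmic rays** are 1–2 band spikes. A band is replaced by the local median
  when it (a) exceeds the 11-band running median by more than `cosmic_ray_z`
  (default 8) robust standard deviations, (b) belongs to an excursion at most
  two bands wide, and (c) also jumps by the same margin above its immediate
  neighbors. Criterion (c) exists because on very low-noise data the robust
  residual scale collapses toward zero and a smooth peak apex would otherwise
  satisfy (a)–(b) and get clipped.
* **Rolling-ball baseline.** The background estimate is a grey-scale opening
  with a flat structuring element of half-width `ball_radius` bands (default
  100): a running minimum followed by a running maximum. The opening never
  exceeds the signal, so the corrected spectrum is non-negative, and
  `corrected + baseline` reconstructs the input exactly. Like any
  finite-window morphological estimate it is distorted within one radius of
  either end, and it undershoots smooth concave curvature by roughly
  `|f''| r² / 2`; the default trim window of 669–1707 cm⁻¹ removes the border
  regions, and the default radius keeps the curvature term below a few percent
  of typical peak amplitudes for fluorescence-like baselines.
* **SNV** uses the sample (n−1) standard deviation; a one-line config change
  selects nothing else. Zero-variance spectra raise an error naming the
  spectrum.
* **Positivity shift.** Because a Gaussian is strictly positive, the single
  global minimum over all bands of all training spectra is subtracted. The
  offset is part of the trained model and is reused verbatim on held-out
  cohorts (`apply_offset()`), so no statistic of a testing cohort ever enters
  the transform.

## Consensus peaks and Gaussian fitting

Candidates are local maxima of the lightly smoothed spectrum (Savitzky–Golay,
7 bands) above a height threshold. Candidates from all spectra are pooled and
clustered greedily: the position supported by the most spectra within
±2 cm⁻¹ anchors a cluster, each spectrum contributes its nearest candidate,
and clusters present in at least 50% of spectra become consensus peaks.

Two defaults here deserve justification:

* **Height threshold** (default 25% of the dataset's 99th-percentile
  intensity). The positivity shift subtracts a *global* minimum, which leaves
  peak-free background regions sitting well above zero — typically 15–25% of
  the intensity range on SNV-scale data. A threshold below that background
  level admits every smoothed noise maximum as a candidate, and under a
  ±2 cm⁻¹ tolerance those random positions aggregate into hundreds of fake
  consensus peaks on noisy cohorts. The threshold is a per-dataset empirical
  quantity; the default is deliberately scale-aware and configurable.
* **Fitting window.** For each consensus peak the inflection points of the
  cohort mean spectrum give a width estimate σ₀ = (right − left)/2, and the
  fitting domain is fixed at center ± 3σ₀ *for every spectrum*. Per-spectrum
  windows sized from per-spectrum (noisy) σ₀ estimates were measured to
  inflate the variance of the fitted widths about four-fold, because the
  window size modulates how much background pedestal enters each fit. The
  per-spectrum data still provide the three starting values: the local
  maximum's height and position, and the per-spectrum inflection-based σ₀.

Inflection detection scans the smoothed second derivative outward from the
peak for its first sign change, bounded by the nearest flanking local minimum;
if none occurs (shoulders, overlaps), the half-maximum crossing is used and
flagged. The signal is smoothed over 7 bands but the second derivative over
15: a curvature filter amplifies stochastic noise far more than a smoothing
filter, and the wider support is what keeps the located inflections within
2 cm⁻¹ of μ ± σ in ≥95% of noisy replicates while still biasing the noiseless
answer by less than one grid step.

The Gaussian `A·exp(−(x−μ)²/2σ²)` is fitted by bounded Levenberg–Marquardt
least squares (`minpack.lm`), with `A ≥ 0`, `μ` inside the window, and `σ` at
most the window width. A fit that fails or worsens the starting residual is
returned unconverged carrying its starting values, and the feature table's
quality mask flags it.

**Normalization of the fitted values.** Each feature column (height@center,
width@center) is standardized across spectra by default. The row-wise
alternative — SNV over each spectrum's concatenated height+width vector — is
available (`snv_axis = "row"`), but for a short vector of mixed units (
intensity-scale heights, cm⁻¹-scale widths) the row moments are driven by
feature content rather than by any per-spectrum nuisance factor, so a row-wise
SNV leaks amplitude variability into the width features; this measurably
degrades width-based classification on the built-in benchmarks.

## Feature selection and classification

Each feature family is ranked by the absolute coefficients of an
L1-regularized linear SVM with squared hinge loss,
`min ||w||₁ + C·Σ max(0, 1 − yᵢ(xᵢ'w + b))²`, solved by accelerated proximal
gradient descent with backtracking (the intercept is unpenalized; columns are
standardized internally so `C` has one scale across feature kinds). Zero
coefficients keep their input order at the tail; ties break toward the lower
wavenumber. Intensity rankings then pass through neighborhood removal: accept
the top feature, delete every feature within ±`n_neighbor` cm⁻¹ of it, and
repeat — adjacent bands are strongly correlated and carry the same
information. Peak features skip this step since they are already one pair per
consensus peak. The top `k_intensity` and `k_peak` survivors are concatenated
and passed to an RBF-kernel SVM (`e1071`).

Hyperparameters (`k_intensity`, `k_peak`, `C_intensity`, `C_peak`, `C_rbf`,
`γ`, `n_neighbor`) are tuned by a randomized grid search under five-repeat
five-fold cross validation, with folds partitioned **by patient**: spectra
from one patient are correlated, and ungrouped folds would leak patient
identity into validation scores (grouping is configurable off). Within every
training fold the entire pipeline — positivity offset, consensus registry,
Gaussian fits, rankings, selection, classifier — is refit from scratch;
validation AUC is pooled per repeat and averaged across repeats. Two grids
ship with the package: `default_hyper_grid()` mirrors the method's published
bounds, while `benchmark_hyper_grid()` extends the `C` ranges upward (L1
strengths to 1, `C_rbf` to 10). The extension matters because with the
objective above and standardized columns, `C ≤ 10⁻⁴` forces the all-zero
coefficient vector on cohort-sized data, making the ranking vacuous; the
method's own published per-task optima include values of exactly this larger
magnitude (RBF costs of 2–5, L1 strengths up to 10⁻²), so the wider grid is
what its selection behavior implies in practice.

## Evaluation

`roc_curve()` builds the empirical ROC over all distinct thresholds
(`score ≥ threshold` ⇒ positive); the AUC is the Mann–Whitney concordance
with midranks for ties. Operating points use the ROC point closest to the
(0, 1) corner (ties: higher sensitivity, then lower threshold; distances are
compared at 12 significant digits so exact geometric ties cannot be broken by
floating-point noise). By default each evaluation derives its threshold from
its own ROC; carrying the training threshold instead is a config switch
(`threshold_policy = "training"`). Accuracy, sensitivity and specificity are
reported in percent, AUC × 100; a dataset missing one class flags the
undefined rate as not-applicable rather than reporting zero.

Two models scored on the same samples are compared with the paired DeLong
test: per-observation placement values give each AUC as a mean, the variance
of the AUC difference follows from the empirical covariances of the paired
placements within each class, and the p-value is two-sided normal. Ties use
the midrank convention throughout, matching the AUC itself.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` draws, per spectrum: a baseline (3rd-degree polynomial
plus a decaying exponential, reproducing the steep low-wavenumber gradient
that motivates border trimming), Gaussian peaks from a class-conditional
library (heights scaled by a per-patient log-normal factor shared across a
patient's spectra; widths and presence drawn per spectrum; centers optionally
wandering by `center_jitter_sd` — real Raman band positions shift by a few
cm⁻¹ between samples, which is exactly why consensus detection carries a
±2 cm⁻¹ tolerance), additive Gaussian noise, and occasional one-band
cosmic-ray spikes. Every drawn parameter is recorded, and generation is
bit-reproducible from the seed.

The benchmark tiers (`default_two_class_benchmark()`): *separable* plants two
class-differential heights (ratio 1.5 at 1004 and 1245 cm⁻¹) and one
differential width (σ ratio 1.3 at 1450 cm⁻¹) over eight shared tissue-like
peaks at noise sd 0.02 with 20 patients per class per cohort; *moderate*
halves and *hard* quarters the effects (the latter at doubled noise). The
*width-only* variant equalizes all height distributions and leaves only width
differentials (σ ratio 1.3 at 1094 and 1450 cm⁻¹), while making the nuisance
structure demanding: height variability 0.25, patient effect 0.3, width
variability 0.5, center jitter 3 cm⁻¹, the six non-differential bands present
in only 70% of spectra, noise 0.08, and 14 patients per class — the size of
a small disease class in multi-center prostate cohorts. That nuisance
structure is the point of the construction: with fixed centers, stable
amplitudes and ever-present neighbors, a fixed-band intensity on a peak
flank reads the width directly and a band-based model ties the fitted-width
model; under positional wander, amplitude variability and intermittent
neighboring bands the flank intensity confounds several latent quantities
while a fitted σ is invariant to them.

Passing benchmarks on these cohorts therefore demonstrates the pipeline's
statistical machinery, leakage hygiene and the width-signal mechanism — not
performance on real tissue: the simulator has no overlapping-band congestion,
no instrument line-shape or calibration drift, no heteroscedastic shot noise,
and its class differences are exactly Gaussian-peak-shaped.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use three simulated cohorts of 20
patients per class (4 spectra each, averaged to one core spectrum per
patient), a randomized-search budget of 24 points over the benchmark grid,
and five-repeat five-fold patient-grouped CV; the width-only comparison uses
14 patients per class, three repeats and a budget of 12. These sizes were
chosen so a full three-mode experiment completes in well under a minute on a
single core while every fold retains at least two patients per class.
Per-fold feature tables and per-(fold, C) L1 rankings are cached during the
grid search; caching only avoids recomputation and cannot change results.
Degenerate inputs are handled explicitly: empty peak lists, single-class
labels, zero-variance spectra and sub-five-band fitting windows raise typed
errors; `k` beyond availability truncates with a warning; a fitting window
too narrow for the grid is widened to a minimum of a few bands.

## Known limitations

* The Gaussian model carries no additive offset, so fitted heights and widths
  absorb part of the shifted background pedestal; widths are consequently
  biased upward. Classification uses them comparatively, where a shared bias
  is harmless, but the fitted σ should not be read as a physical linewidth.
* Overlapping bands are fitted one at a time within their windows, not
  jointly deconvolved; strongly overlapped doublets shift both fits.
* The L1-SVM solver is first-order and stops at a relative objective change
  of 10⁻⁶ — ample for ranking stability, but not a high-precision interior
  point method.
* Lorentzian/Voigt line shapes, probability calibration, multi-class tasks
  and vendor instrument file formats are out of scope.
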