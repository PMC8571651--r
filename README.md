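# ramanpeaks

Tissue classification from Raman micro-spectra with a peak-fitting
dimensional reduction step. The package is aimed at spectroscopists and
computational pathologists who train classifiers on confocal Raman
measurements of tissue (e.g. separating benign from malignant prostate
epithelium) and want engineered features that are more interpretable and less
noise-sensitive than raw per-band intensities.

## The method

A Raman spectrum is a vector of intensities over Raman shifts (cm⁻¹). After
preprocessing — accumulation summing, cosmic-ray despiking, rolling-ball
(morphological opening) baseline removal, standard normal variate (SNV)
normalization, per-core averaging, and a dataset-wide positivity shift — the
package extracts two feature families:

* **Intensity features**: the SNV intensity at individual bands.
* **Peak features**: *consensus peaks* are band positions where at least 50%
  of the cohort's spectra show a local maximum within ±2 cm⁻¹. For each
  consensus peak and each spectrum, a Gaussian `A·exp(−(x−μ)²/2σ²)` is fitted
  by bounded nonlinear least squares over the peak's window, with starting
  values from the spectrum's own maximum and inflection points
  (σ₀ = half the inter-inflection distance). The fitted height `A` and width
  `σ` become features.

Each family is ranked by the absolute coefficients of an L1-regularized
linear SVM (`min ||w||₁ + C Σ max(0, 1 − yᵢ(xᵢ'w+b))²`); intensity rankings
additionally pass through ±`n_neighbor` cm⁻¹ redundancy removal. The top
`k_intensity` and `k_peak` features feed an RBF-kernel SVM
(`exp(−γ‖u−v‖²)`), tuned by a randomized grid search under five-repeat
five-fold *patient-grouped* cross validation maximizing ROC AUC. Evaluation
reports accuracy, sensitivity and specificity at the ROC point closest to the
(0, 1) corner, plus AUC, and compares models on the same samples with the
paired DeLong test.

A built-in simulator (`generate_cohort()`) produces multi-patient synthetic
Raman cohorts — Gaussian peak libraries with class-dependent heights, widths
and presence probabilities, fluorescence-like baselines, noise, cosmic-ray
spikes and per-patient effects — with full ground truth, so the entire
pipeline is testable without instrument data.

## Worked example

```r
library(ramanpeaks)

# three synthetic cohorts: one training, two held-out
train <- generate_cohort(default_two_class_benchmark("separable", seed = 101,
                                                     cohort = "train"))$set
cfg <- experiment_config(
  task     = "demo",
  training = train,
  testing  = list(
    t1 = generate_cohort(default_two_class_benchmark("separable", seed = 102,
                                                     cohort = "t1"))$set,
    t2 = generate_cohort(default_two_class_benchmark("separable", seed = 103,
                                                     cohort = "t2"))$set),
  grid   = benchmark_hyper_grid(), budget = 24,
  scheme = list(folds = 5, repeats = 5), seed = 7)
res <- run_experiment(cfg)

res$models$peak
#> <trained_model [peak] demo: 16 features, training AUC 1.000>
res$reports$combined$t1
#> <eval_report demo [combined]: acc 100.0% sens 100.0% spec 100.0% AUC 100.0>
sapply(res$reports, function(r) c(t1 = r$t1$auc, t2 = r$t2$auc))
#>    intensity peak combined
#> t1       100  100      100
#> t2       100  100      100
```

The separable benchmark plants two class-differential peak heights and one
differential width over eight shared tissue-like bands; all three feature
modes reach AUC 100 on both held-out cohorts (reported ×100, as percentages),
and the combined model never falls below the better single-family model —
the property the method is built around. Harder tiers
(`default_two_class_benchmark("hard")`) and a width-only variant (class
signal in peak shape alone) probe the regimes where the families differ; on
the width-only benchmark the peak model outperforms the intensity model.

A thin command-line wrapper ships in `inst/cli/ramanpeaks.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ramanpeaks.R",package="ramanpeaks"))')" \
    simulate --out data/ --seed 4
```

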