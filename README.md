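# qusresponse

Predicting breast-tumor response to neoadjuvant chemotherapy from
*pre-treatment* quantitative ultrasound (QUS) is attractive because raw
radiofrequency (RF) ultrasound is cheap, fast and contrast-free: after
normalizing backscattered power spectra against a calibrated reference
phantom, spectral fits yield tissue-characterizing parameters that are
independent of the scanner's transfer function. `qusresponse` implements that
entire analysis chain as a reusable, tested R package, together with a
physics-based synthetic RF cohort generator so that every stage can be
validated against known ground truth — the original clinical cohorts behind
this family of studies are confidential and cannot ship with any analysis
code.

The pipeline, end to end:

1. **Synthetic RF cohorts** (`generate_cohort`, `simulate_rf_frame`,
   `make_reference_frame`): point-scatterer speckle simulation with Gaussian
   pulses (6 MHz center, 3–8 MHz band, 40 MHz sampling), frequency-dependent
   attenuation, spherical Gaussian form-factor spectral shaping, a
   two-class cohort (37 nonresponders vs 137 responders, 4–7 image planes
   per patient) and a 0.576 dB/MHz·cm, 1488 m/s reference phantom.
2. **Spectral estimation** (`block_power_spectrum`, `normalize_spectrum`,
   `fit_spectral_params`): Hann-gated scan-line periodograms, reference-
   phantom normalization with round-trip attenuation compensation
   `4·(α_s − α_r)·f·d` dB, and the three linear-fit parameters over the
   −6 dB band —

   `NPS(f) ≈ SI + SS·f`, `MBF = SI + SS·f_c`

   (midband fit MBF in dB, spectral slope SS in dB/MHz, 0-MHz intercept SI).
3. **Scatterer parameters** (`estimate_bsc`, `fit_gaussian_form_factor`):
   backscatter coefficient via the reference-phantom transfer, then a
   linearized fit of the spherical Gaussian form-factor model

   `BSC(f) = C · f⁴ · exp(−0.827 k² a_eff²)`, `k = 2πf/c`

   giving the average scatterer diameter `ASD = 2·a_eff` (µm) and average
   acoustic concentration `AAC = 10·log₁₀(C/a_eff⁶)` (dB).
4. **Parametric maps** (`plan_windows`, `build_maps`, `render_map_image`):
   sliding square analysis blocks (2.2 mm side, configurable overlap up to
   the 94% protocol value) over the tumor core + 5 mm margin ROI; five
   co-registered maps (ASD, AAC, MBF, SS, SI), cropped, min–max scaled and
   bilinearly resized to 224 × 224 images.
5. **Frozen-backbone features** (`extract_features`,
   `average_tumor_features`): a frozen convolutional feature extractor with
   the 7 × 7 × 2048 output contract of a ResNet50V2-class final
   convolutional stage, flattened to 100,352 features per image and averaged
   across a tumor's image planes. The packaged default backbone is a
   deterministic fixed-seed random-projection network; any network honoring
   the same contract can be injected via `backbone()`.
6. **Selection, balancing, classification** (`nonzero_filter`, `k_rule`,
   `select_k_best`, `smote_balance`, `split_cohort`, `train_svm`,
   `crossvalidate`, `evaluate_pipeline`): 90%-nonzero prevalence filter,
   ANOVA F-score k-best with `k = round(√N)` (13 for 174 patients), SMOTE
   oversampling of the minority class on training rows only, stratified
   80/20 split, linear SVM, and per-class precision/recall/F1 plus balanced
   accuracy from the test confusion matrix. The nonresponder (NR) class is
   the positive class throughout.

## Worked example

```r
library(qusresponse)

## confusion-matrix metrics for a 35-patient test set:
## 7 nonresponders of whom 5 are caught, all 28 responders correct
cm <- matrix(c(5, 2, 0, 28), 2, byrow = TRUE,
             dimnames = list(true = c("NR", "RR"),
                             predicted = c("NR", "RR")))
rep <- metrics_from_confusion(cm)
rep$per_class[, 1:4]
#>   class precision recall f1
#> 1    NR       100     71 83
#> 2    RR        93    100 97
rep$balanced_accuracy
#> [1] 86
```

100% NR precision means no responder was mislabeled a nonresponder; 71% NR
recall means 5 of the 7 true nonresponders were caught; balanced accuracy 86
is the mean of the two class recalls (71 and 100).

A miniature imaging run, from RF physics to a feature table:

```r
cfg <- cohort_config(n_nr = 4, n_rr = 4, frames_range = c(4, 4),
                     geometry = scan_geometry(n_lines = 80,
                                              lateral_spacing = 0.2,
                                              depth_offset = 4,
                                              depth_max = 22))
cohort <- generate_cohort(cfg, seed = 17)
feats <- cohort_features(cohort, parameter = "SS", overlap = 0.5,
                         max_frames = 2)
dim(feats$X)
#> [1]      8 100352
```

At full cohort scale the classifier is exercised on feature-level synthetic
cohorts:

```r
fc <- simulate_feature_cohort(n_nr = 37, n_rr = 137, effect_size = 2,
                              seed = 31)
res <- evaluate_pipeline(fc$X, fc$y, seed = 31)
res$confusion
#>     predicted
#> true NR RR
#>   NR  7  0
#>   RR  0 28
```

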