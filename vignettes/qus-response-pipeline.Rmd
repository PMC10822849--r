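---
title: "Quantitative ultrasound response prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound response prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qusresponse)
```

`qusresponse` chains four scientific components: a physics-based RF speckle
simulator, reference-phantom QUS spectroscopy, frozen-backbone image
features, and an imbalance-aware linear classifier. This vignette is the
package's account of each model, why its defaults are what they are, and
where the genuinely open design decisions were settled.

## The RF simulation model

Tissue microstructure is represented as a 2-D point-scatterer field. Each
scatterer at depth $d$ contributes a Gaussian-modulated cosine echo at the
round-trip delay $2d/c$, weighted laterally by a Gaussian beam profile, and
spectrally shaped by two frequency-dependent filters:

* **Attenuation.** The round-trip echo *power* at depth $d$ (cm) falls by
  $4\,\alpha f d$ dB ($f$ in MHz, $\alpha$ in dB/MHz·cm). This is the
  convention under which the classical reference-phantom compensation term
  $+4(\alpha_s-\alpha_r) f d$ exactly cancels the attenuation difference;
  simulator and estimator share it by construction. Attenuation is applied
  piecewise in 0.5 mm depth segments, a granularity that keeps the worst-case
  within-segment error below 0.1 dB across the band.
* **Scattering.** Echo amplitude is multiplied by
  $\exp(-0.827 k^2 a^2/2)$ so that echo *power* carries the spherical
  Gaussian form factor $\exp(-0.827 k^2 a^2)$ that the backscatter model
  assumes ($k = 2\pi f/c$, $a$ the effective scatterer radius). A
  frequency-independent scalar would leave the spectral *shape* blind to
  scatterer size, and no size estimator could recover anything; the
  frequency-dependent filter is therefore part of the model, not an
  embellishment. Scatterer impedance amplitude defaults to the Rayleigh
  volume scaling $(a/15\,\mu m)^3$, which makes echo power proportional to
  $n a^6$ — exactly the quantity the acoustic-concentration estimate
  normalizes by. Without it, concentration estimates would inherit a
  spurious $-60\log_{10} a$ term.

The pulse is Gaussian with its $-6$ dB power bandwidth spanning 3–8 MHz
around a 6 MHz center, sampled at 40 MHz. Implementation is an impulse-train
accumulation per (depth-segment × radius-group), convolved in the frequency
domain with a zero-phase pulse kernel; echoes land within half a sample of
their true delay. Additive white Gaussian noise is injected at a
configurable frame-level SNR (default 30 dB). The model deliberately omits
3-D/elevational beam effects, focusing, nonlinear propagation and multiple
scattering.

Key tunables: `beam_sigma` (lateral beam σ, mm; default 0.1) controls
lateral speckle decorrelation and hence the number of statistically
independent scan lines per analysis block — the dominant driver of
spectral-estimate variance; tissue sound speed defaults to 1540 m/s, the
phantom's to its calibrated 1488 m/s (the phantom frame is recorded over the
same *time* gate, so block gates align sample-for-sample).

## Spectral estimation and normalization

Per analysis block, each scan-line segment is Hann-tapered, zero-padded to
the next power of two at least four times the gate length, and transformed;
magnitude-squared line spectra are arithmetically averaged and converted to
dB. Zero-power bins are clamped at $-200$ dB and flagged; any clamped bin
inside the fit band invalidates the block rather than biasing a fit.

Normalization subtracts the reference-phantom block spectrum measured over
the same axial gates (cancelling the system transfer function and beam
terms) and adds the attenuation compensation $4(\alpha_s-\alpha_r) f d$ dB.
The tissue attenuation used for compensation defaults to 1.0 dB/MHz·cm — a
conventional soft-tissue literature value for when the true value is
unknown — while synthetic experiments pass the simulator's known value
(cohort default 0.75 dB/MHz·cm, mid-range for breast parenchyma).

MBF/SS/SI come from ordinary least squares of the normalized dB spectrum
against frequency restricted to 3–8 MHz; `MBF = SI + SS·f_c` holds to
machine precision because MBF is evaluated from the fitted coefficients.
The backscatter coefficient transfers the normalized spectrum onto the
phantom's analytic curve, $BSC_s(f) = BSC_r(f)\,10^{NPS(f)/10}$, with
$BSC_r$ computed in closed form from the phantom's bead radius and density
under the same Gaussian form-factor model — keeping the oracle analytic
rather than empirical. The form-factor fit is linearized:
$\ln(BSC/f^4)$ regressed on $k^2$, slope $\to a_{\mathrm{eff}}$
(ASD $= 2a_{\mathrm{eff}}$), intercept $\to C$, reported as
AAC $= 10\log_{10}(C/a_{\mathrm{eff}}^6)$ so AAC tracks concentration. A
non-negative slope means no Gaussian decay is present; the fit signals
failure explicitly instead of returning a boundary value. Linearized least
squares was chosen over nonlinear fitting because it is deterministic,
closed-form, exact on model-generated data, and standard practice for this
model family.

## Windows, maps and images

Analysis blocks are square, 2.2 mm a side by default. The alternative
ten-wavelength prescription ($10 c/f_c \approx 2.57$ mm at 6 MHz in tissue)
is also supported (`block_side = NULL`); the two conventions are not
numerically equivalent, and the explicit millimetre figure takes precedence
because it is concrete. Step size is $(1-\mathrm{overlap})\cdot$side; the
protocol overlap of 94% gives a 0.132 mm step. Package experiments use 50%
overlap: at 94% adjacent blocks share nearly all their data, multiplying
compute roughly 180-fold while adding almost no independent information to
block-median summaries.

The ROI is an elliptical tumor core plus a 5 mm morphological-dilation
margin ring, rasterized on the RF grid. Maps hold one value per block center
with an explicit validity mask — failed blocks are flagged, never silently
zeroed — and a build aborts only if more than half the blocks fail.

For the feature extractor, a map is cropped to the ROI bounding box, valid
values are min–max scaled to $[0,1]$ per image, out-of-ROI pixels are set to
0, and the raster is bilinearly resized to 224 × 224. Per-image min–max
scaling with 3-channel replication of the scalar raster was chosen over
colormapped RGB: it is invertible and removes the colormap as a hidden
hyperparameter, at the cost of discarding absolute parameter levels — class
information must then live in spatial structure, which is why classifier
calibration at cohort scale uses feature-level synthetic cohorts (below).

## The frozen backbone

Feature extraction is injected behind a one-function interface: any
deterministic map from a 224 × 224 × 3 array to a 7 × 7 × 2048 activation
block qualifies, and the flattening order (row, column, channel; row-major)
is fixed and tested because selected feature indices depend on it. The
packaged default, `random_projection_backbone()`, average-pools each of the
49 patch cells to 8 × 8, projects the 192-dimensional descriptor through a
fixed-seed Gaussian matrix and applies a ReLU. Frozen random-projection
features are a legitimate, well-studied feature family; what matters for
this pipeline — determinism, continuity, rectification (exact zeros for the
prevalence filter), the exact 100,352-length contract — is preserved, and an
ImageNet-pretrained network can be swapped in through `backbone()` without
touching any downstream code. Inputs are scaled to $[-1, 1]$ inside
`extract_features`, the canonical preprocessing of the backbone family the
interface mirrors. Per-slice vectors are averaged into one tumor vector
*after* extraction, matching the stated order of operations of the protocol.

## Selection, balancing and evaluation

* **Prevalence filter:** keep features ≥ 90% nonzero across training rows;
  "nonzero" is exact inequality — rectified activations make exact zeros
  meaningful. The filter is fit on training rows only (the protocol is
  explicit about train-only balancing; train-only selection is the choice
  here for both steps, closing the leakage path).
* **k-best:** per-feature one-way ANOVA F between the two classes;
  `k = round(√N)` (13 at N = 174). Perfect separators (zero within-class
  variance) rank first at $F = \infty$; constant columns score 0; ties break
  toward the lower index. Selection is fit once on the non-test rows, not
  per CV fold; the fold-wise variant can be composed from the exported
  pieces.
* **SMOTE:** synthetic minority rows $x + u(x_{nn} - x)$, $u \sim U(0,1)$,
  $x_{nn}$ among the 5 nearest minority neighbours (reduced to minority−1
  when necessary); originals preserved verbatim; a singleton minority is an
  explicit error, not a silent duplication.
* **Split and SVM:** stratified 80/20 with largest-remainder per-class
  allocation (ties toward the larger class), which yields the canonical
  35-patient, 7 NR / 28 RR test set at N = 174. The SVM is linear with
  cost 1 and no feature scaling; prediction is the sign of the decision
  function; an all-constant feature matrix yields an explicit
  majority-class predictor, flagged as degenerate. Five-fold
  cross-validation applies SMOTE inside each fold's training part only.
* **Metrics:** per-class precision/recall/F1 and balanced accuracy (mean of
  per-class recalls, computed before rounding), reported as integer percent
  with halves rounded away from zero; zero-denominator cases are `NA`
  (undefined), never 0. NR is the positive class.

## What the synthetic data does and does not show

The generator emulates: the two-class 37/137 cohort structure, 4–7 image
planes per patient, the acquisition pulse and phantom constants, speckle
statistics with ≥ 5 scatterers per resolution cell, and class separation
through scatterer radius (nonresponders larger: 32 ± 3 µm vs 22 ± 3 µm
effective radius) and number density (nonresponders sparser: 35 ± 4 vs
60 ± 6 mm⁻²). No quantitative description of how the two clinical classes
differ in scatterer statistics exists, so these effect sizes are stipulated
to give visibly separable spectral-slope maps — passing recovery and
separability tests demonstrates that the *estimators and pipeline* behave
correctly, not that clinical effect sizes are this large.

Frames default to a desk-scale field of view (≈19 mm × 20 mm at 96 scan
lines in the experiments; the clinical protocol's 6 cm × 4–6 cm frames are
supported but unnecessary for validating estimators). Problem sizes used by
the tests and the acceptance script: a 20-patient recovery cohort (two arms
of 10: five radius levels × 2 at fixed density, five density levels × 2 at
fixed radius — isolating each parameter, since in a two-class cohort radius
and density co-vary by class and AAC's residual radius sensitivity would
confound a density rank test), 200-replicate noise studies, and 50-seed
null-calibration runs on full-size 174 × 100,352 feature cohorts. The
classifier's null calibration (mean test balanced accuracy ≈ 50% on
label-free cohorts) and separated-cohort behaviour (≥ 90%) are
property-based substitutes for the confidential clinical benchmark, which
no synthetic cohort can reproduce.

## Numerical choices and degenerate inputs

dB floor $-200$ with per-bin clamp flags; FFT length next power of two
≥ 4× gate length; Hann taper from the standard DSP library; bilinear
interpolation for image resizing; constant-valued maps render as a constant
image (scaled to 1); empty scatterer fields simulate to an all-zero frame;
negative SNR configurations, out-of-geometry scatterers, mismatched
frequency grids, single-class training data and sub-2-member minorities all
raise typed errors (`qus_*_error` condition classes) rather than returning
numbers. All stochastic entry points take explicit seeds, derive child seeds
below $2^{31}$, and restore the caller's RNG state.

## Known limitations

The 2-D impulse-train model has no elevational dimension, no focusing or
diffraction, and its absolute BSC scale is meaningful only relative to the
phantom model. Block-level ASD estimates are upward-biased at low
size-contrast (speckle noise truncates the fit at zero decay), so recovery
is validated as rank-monotonicity rather than absolute accuracy. Per-image
min–max scaling erases absolute parameter levels from the map images. The
default backbone, while contract-identical, is not an ImageNet-pretrained
network, and transfer-learning claims about natural-image priors are
outside what this package can test.
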