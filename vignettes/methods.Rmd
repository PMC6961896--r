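---
title: "Ultrasound radiomics for lateral lymph-node prediction: models and design choices"
author: "usradiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasound radiomics for lateral lymph-node prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usradiomics)
```

## The problem

Lateral cervical lymph-node metastasis (LNM) in conventional papillary
thyroid carcinoma changes surgical management (lateral compartment
dissection, radioiodine dosing), but its preoperative ultrasound
assessment is strongly operator-dependent. This package implements a
radiomics alternative: quantify the texture of the *primary tumor* on a
single representative B-mode image, select a sparse predictive subset of
those features with penalized logistic regression, and summarize each
patient as one number — the radiomics score — whose discrimination is
then evaluated on an independent validation cohort.

The pipeline has five stages, each exposed as plain functions:
preprocessing (`extract_roi`, `normalize_patch`, `quantize`), feature
extraction (`extract_all_features`), signature fitting (`fit_lasso_cv`,
`build_signature`), scoring (`rad_score`), and evaluation (`roc_auc`,
`cohort_summary`). `run_pipeline()` wires them together.

## Preprocessing

RGB frames are reduced to luminance with the ITU-R BT.601 weights
(0.299, 0.587, 0.114) — the standard "discard hue and saturation,
retain luminance" conversion — and rounded to the nearest integer.
Masks must contain at least 16 foreground pixels forming one
4-connected component; everything outside the mask is excluded from
every statistic.

Normalization is a z-score over the masked pixels (population SD), so
features are invariant to affine intensity rescaling between scanners
and gain settings. A constant ROI has no texture information; it maps
to all-zeros and raises a degeneracy flag rather than erroring, so
degenerate phantoms survive the pipeline. After normalization the
pixels outside the mask are set to 0 (the masked mean), which
guarantees the wavelet channels cannot leak information from outside
the tumor: corrupting any unmasked pixel changes no feature, a property
the test suite asserts directly.

Gray-level quantization uses 32 equal-width bins after clipping the
masked intensities to their 1st–99th percentiles. Thirty-two levels is
the common compromise for co-occurrence statistics on ROIs of a few
hundred to a few thousand pixels: enough levels to resolve texture,
few enough that the G x G matrix is well populated. Both G and the
clip are configurable; the defaults are declared package decisions, as
is everything in this section not fixed by the conversion standard.

## The 730-feature registry

Each patient yields 730 named, ordered features: five channels (the
original normalized patch plus the LL/LH/HL/HH subbands of a
single-level 2-D Haar wavelet transform), and per channel 14
first-order statistics, 22 GLCM statistics at each of four angles
(distance 1), and 11 GLRLM statistics at the same angles:
5 × (14 + 22·4 + 11·4) = 730. The decomposition is data-driven and
reconfigurable; the default registry size is asserted when the package
loads.

Conventions worth noting:

* GLCM matrices are symmetric (each offset and its negation are
  accumulated) and normalized to unit mass; features are computed per
  angle, not angle-averaged, which is what brings the count to 730.
* GLRLM runs break at masked-out pixels and patch edges; the
  pixel-count identity Σⱼ j·r(i,j) = number of masked pixels holds for
  every direction and is tested property-style.
* Entropies are in bits (log₂); moments are population moments;
  kurtosis is the raw fourth standardized moment (3 for a Gaussian),
  not excess.
* The wavelet is the orthonormal Haar pair. With even dimensions the
  single-level transform is an exact 2×2 block transform with perfect
  reconstruction (tested to 1e-6); odd dimensions are edge-replicated
  first. No pre-installed R wavelet package exists in the supported
  environment, and for a single Haar level a direct implementation is
  smaller than a dependency. The mask is downsampled by a 2×2
  "block-any" rule, and each subband is re-quantized independently
  with the same G and clip before its texture matrices are built.
* Statistics whose denominators vanish on constant regions (GLCM
  correlation, the information measures, skewness/kurtosis) return 0
  and are recorded in a per-feature degeneracy attribute instead of
  producing NaN.

The GLCM and GLRLM builders are verified against independent loop-based
enumeration oracles: exhaustively for every two-level patch up to
3×4/4×3, and over a broad fixed-seed sample of the 65,536 4×4 patches
with random masks. Exhausting all 4×4 patches adds nothing but runtime;
the sampled sweep plus full enumeration of the smaller shapes already
covers every run/pair topology the builders distinguish.

## Signature model

Features with zero variance or non-finite values across the training
cohort are removed first, with a report naming each removed feature and
the reason. Remaining features are standardized with training-cohort
means and SDs only; the validation cohort never contributes to the
constants, and a permutation test in the suite confirms validation
labels cannot influence any signature parameter.

The L1-penalized logistic path is fit by glmnet (objective
−(1/n)·loglik + λ‖β‖₁, intercept unpenalized) over a 100-point
log-spaced grid from λ_max down to 10⁻³λ_max. Cross-validation is a
10-fold stratified loop implemented in the package: per fold, the path
is refit on the complement and evaluated on the held-out fold; the
per-λ metric is the mean across folds with its standard error. The
default metric is held-out AUC — matching a selection curve plotted as
CV AUC versus log λ — with binomial deviance available by
configuration. λ_min is the grid point attaining the CV optimum; ties
break to the largest (sparsest) λ. Fold assignment derives from a
fixed seed (default 0), so identical data, seed and grid give identical
λ_min, coefficients and scores.

Two properties of this design are worth knowing. First, with very
strong class separation and small folds the held-out AUC can saturate
at 1.0 along the entire path; the sparsest-λ tie-break then selects the
null model. This is the correct consequence of the stated tie-break
and disappears at realistic effect sizes and cohort sizes. Second,
under a global null the AUC metric is noisy around 0.5 and its argmax
selects small spurious models more often than deviance does; the
deviance metric is the conservative choice for null-behavior studies,
and the test suite uses it for that property.

The fitted signature stores the intercept, the nonzero coefficients on
the standardized scale, λ, and the per-feature standardization
constants — everything needed to compute
`Rad-score = β₀ + Σ βᵢ(xᵢ−μᵢ)/σᵢ` for a new patient. Serialization is
JSON at full precision; a round-trip reproduces scores exactly. A
missing feature at scoring time is an error, never a silent imputation.

## Evaluation statistics

AUC is computed through the midrank Mann–Whitney identity
(AUC = U/(n₁n₀)), asserted against exhaustive pair enumeration and the
label-swap antisymmetry AUC(y) + AUC(1−y) = 1. The 95% CI uses
DeLong's placement-value variance estimator, cross-checked in the
suite against pROC and shown to cover a true AUC of 0.7 at the nominal
rate over 1,000 simulated two-Gaussian score sets (n = 100/100); a
percentile bootstrap is available by configuration.

`mann_whitney()` uses exact enumeration of all group assignments when
n₁+n₂ ≤ 10 (ties handled exactly) and a tie-corrected normal
approximation (no continuity correction) otherwise. `chi_square()` is
Pearson's test; for 2×2 tables the continuity correction is applied by
default, which reproduces the published cohort-table p-value of 0.045
for the 83/317 vs 100/268 lateral-LNM split — uncorrected Pearson
gives 0.037, so the published analysis evidently used the corrected
default of standard statistical software, and this package follows it
(the correction is configurable). Both choices, and the two-sided
α = 0.05 convention, are deliberate.

## The synthetic cohort generator

Real study data are not shipped; the generator emulates the study's
*structure* so the pipeline is testable end to end:

* images are 128×128 8-bit; tumors are uniform-random ellipses
  (semi-axes 8–20 px) strictly inside the frame;
* speckle is unit-mean multiplicative Gamma noise (shape k = 4)
  smoothed by a Gaussian of width s, on a smooth base intensity field
  with a gentle random gradient — the standard first-order mimic of
  B-mode texture;
* the class signal enters only through the speckle correlation length:
  s = s₋ + δ·label with s₋ = 1 px. δ = 0 is the null configuration;
  δ = 2 produces a texture effect the GLCM contrast feature alone
  separates with AUC > 0.8;
* labels are Bernoulli with prevalence 0.21 (training convention) or
  0.27 (validation), matching the published cohort prevalences;
  covariates (age truncated-normal 45 ± 13 on [17, 80], sex ≈ 15%
  male, log-normal tumor size around 17 mm, central-LNM ≈ 57%) emulate
  the published cohort tables but carry no image signal by default —
  the signature is image-only. An optional flag couples central-LNM
  status to the label with the published odds direction for
  table-reproduction demonstrations.

All randomness flows from one seed; generation restores the caller's
RNG state. What the generator does **not** emulate: scanner point-
spread functions, attenuation/shadowing, anisotropic speckle,
JPEG-compression artifacts, reader variability in segmentation, or any
correlation between covariates and texture. Passing tests therefore
demonstrate the pipeline's statistical machinery — masking discipline,
selection, no-leakage, calibration — on speckle-like texture, not
clinical performance on real ultrasound.

## Problem sizes and calibration checks

The acceptance suite runs the full study replica at the published
cohort sizes (400 training / 368 validation) over 20 seeds under the
null (δ = 0), where the end-to-end validation AUC stays within
[0.45, 0.58], and once under δ = 2, where it exceeds 0.65 by a wide
margin; training AUC exceeds validation AUC on average, the optimism
pattern any honestly validated radiomics signature shows. Selection
recall for five planted
informative features among 730 at n = 400 averages above 0.8 over 20
seeds. Fixed-λ coefficients match a restarted Nelder–Mead optimization
of the penalized likelihood to 1e-4 on a 20×3 problem.

## Known limitations

* Feature definitions follow one consistent reconstruction of a
  730-feature registry (14/22×4/11×4 over five channels); other
  radiomics toolkits differ in statistic lists, angle-averaging and
  discretization conventions, so absolute feature values are not
  interchangeable across toolkits.
* Whether quantization should precede or follow the wavelet transform
  per subband is a genuine convention choice; this package quantizes
  each subband independently after transforming the normalized patch.
* The CV-AUC selection criterion degenerates under perfect separation
  (see above); use the deviance metric when studying null behavior.
* Only first-order, texture-matrix and single-level wavelet features
  are implemented — no shape/margin/position features, no
  Laplacian-of-Gaussian channels, no multi-level decompositions.
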