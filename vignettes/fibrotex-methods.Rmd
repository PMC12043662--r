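---
title: "Texture-based classification of fibrillar collagen: models and methods"
author: "fibrotex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based classification of fibrillar collagen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Airway remodeling in asthma is accompanied by increased deposition and
structural reorganization of fibrillar collagens I and III in the
extracellular matrix. Second-harmonic generation (SHG) microscopy
visualizes fibrillar collagen label-free, and the morphological difference
between healthy and remodeled tissue — long, coherently aligned fiber
bundles versus short, fragmented, disordered segments — is a textural
difference. `fibrotex` implements a complete pipeline that turns a set of
grayscale SHG images with binary class labels (control vs. remodeled) into
a trained classifier, via five stages: preprocessing, texture-feature
extraction, outlier cleaning, feature refinement, and classification.

Because donor SHG image sets are rarely shareable, the package also ships a
synthetic fibrillar phantom generator so that every stage of the pipeline
can be exercised, tested and benchmarked with no external data.

# Preprocessing

Images enter as single-channel 8- or 16-bit TIFFs. 16-bit images are
converted to 8-bit, by default with a fixed integer division by 256
(`to8bit(mode = "fixed_shift")`). The alternative per-image min–max
rescaling (`"minmax"`) is provided for parity experiments, but it is not
the default because per-image rescaling destroys cross-image intensity
comparability, which the subsequent low-signal filter relies on.

The low-signal filter (`filterLowSignal`) rejects an image when its mean
8-bit intensity falls strictly below a threshold, 5 by default. "Mean"
is one of several defensible readings of a bare intensity threshold; we use
the mean because it is the standard low-signal criterion, and we keep the
threshold exposed. The inequality is strict: an image whose mean is exactly
5 is kept.

# The 80-feature texture panel

Each image yields exactly 80 features, fixed by a canonical registry
(`featureRegistry()`): 4 first-order statistics (FOS), 24 gray-level
co-occurrence (GLCM), 16 size-zone (GLSZM), 16 run-length (GLRLM), 15
dependence (GLDM) and 5 neighborhood gray-tone difference (NGTDM)
features. The registry is the single source of truth for names, family
membership and column order; every table, selector and report uses its
order, and all tie-breaking falls back to it so results are reproducible
across platforms.

Texture matrices are computed on a quantized image: equal-width binning of
[0, 256) into `nLevels` bins (default 64, configurable 2–256; 256
reproduces the raw 8-bit levels). 64 bins stabilize sparse co-occurrence
statistics at the ~450 px image sizes the pipeline targets.

Directional families (GLCM, GLRLM) are evaluated at 0°, 45°, 90° and 135°
(pixel offsets (0,1), (−1,1), (−1,0), (−1,−1) with a top-left origin) and
averaged *at the feature level* across the four directions. A direction
that admits no pixel pairs (e.g. a vertical scan of a one-row image) is
excluded from the average with a warning. The GLCM is accumulated
symmetrically at inter-pixel distance 1. GLSZM zones use 8-connectivity by
default (4-connectivity available); GLDM uses similarity tolerance
\(\alpha = 0\) and Chebyshev radius 1; NGTDM uses the 8-neighborhood mean
of each pixel's valid in-image neighbors.

Within the feature formulas, gray levels are 1-based row indices, run
lengths and zone sizes are their natural values, and GLDM dependence enters
as (dependence + 1) so that inverse-square weights are always defined.
Entropies are base 2 with \(0 \log 0 = 0\).

The four first-order features are the mean, population variance, skewness
and kurtosis of the raw intensity histogram. The GLDM panel comprises the
14 canonical dependence features plus `GrayLevelNonUniformityNormalized`,
giving 15.

## Degenerate inputs

All zero-denominator conventions are centralized and tested: a constant
image has GLCM Correlation = 1 and MaximalCorrelationCoefficient = 1,
entropies and Contrast 0, MaximumProbability 1; NGTDM Coarseness is capped
at \(10^6\) when \(\sum_i p_i s_i = 0\), while Busyness, Complexity and
Strength fall back to 0 when their denominators vanish; FOS skewness and
kurtosis are 0 at zero variance. No feature is ever NaN.

The maximal correlation coefficient is the square root of the
second-largest eigenvalue magnitude of
\(Q_{ij} = \sum_k p(i,k)\,p(j,k)/(p_x(i)\,p_y(k))\), restricted to occupied
gray levels, with eigenvalues clipped to [0, 1] to absorb numerical noise.

# Outlier cleaning

Features are cleaned column-wise with Tukey fences: quartiles by linear
interpolation between order statistics, fences at \(Q_1 - 1.5\,\mathrm{IQR}\)
and \(Q_3 + 1.5\,\mathrm{IQR}\) (the multiplier is exposed). Values outside
the fences are replaced by the column median computed over all original
values — robust for under 50% contamination and free of two-pass
ambiguity. When the IQR collapses to zero the fences coincide and
replacement is skipped, so near-constant features are never overwritten
wholesale. Medians are preserved by the substitution (exactly for odd
sample counts). The operation is not idempotent in general — substitution
narrows the fences on recomputation — which is intrinsic to IQR cleaning
rather than a defect; it is idempotent whenever the substitution leaves
the quartiles unchanged.

# Feature refinement

Four strategies are implemented, all returning canonical `FeatureSubset`
objects:

* **ANOVA F-test** (`anovaFSelect`): one-way F per feature, top *k*
  (default 10). Zero within-class variance with distinct means ranks
  first; ties break by registry order.
* **Recursive feature elimination** (`rfeSelect`): backward elimination
  with a decision-tree learner, dropping the least important feature each
  round. The automatic stopping rule walks the elimination path and stops
  at the first subset whose cross-validated accuracy drops more than one
  standard error below the best accuracy seen so far, returning the subset
  just before the drop. We deliberately do not take the globally smallest
  subset within one SE of the best: under cross-validation noise a
  one-feature subset is transiently "within one SE" even when two jointly
  necessary features exist, and the elimination-until-drop reading matches
  the procedure's intent. An explicit `nFeatures` override reproduces
  fixed subset sizes.
* **Permutation importance** (`permutationSelect`): a random forest is
  trained on a stratified training portion; each feature's validation
  column is permuted (default 100 repeats) and the mean accuracy drop is
  the score. Selected features are those whose mean drop exceeds zero by
  more than one standard deviation of their drops — a cutoff we had to
  choose, since "important on average" needs an operational form; a top-k
  override is provided. If nothing clears the cutoff the top feature is
  returned so the subset is never empty.
* **Interclass coefficient of variation** (`covSelect`): for two classes
  the population SD of the two class means over their absolute grand mean,
  i.e. \(|m_1 - m_2| / |m_1 + m_2|\), kept when at or above the threshold
  (default 8%). An epsilon guards cancellation of the grand mean. This
  formula is our interpretation of an interclass-CV filter; it is
  documented rather than hidden because published descriptions of the
  method omit the formula.

`poolSubsets` forms the registry-ordered union of several subsets —
idempotent, commutative, associative. `airwayPanels()` ships the four
refined panels reported in a published SHG airway-collagen application of
this pipeline (10 + 9 + 7 + 17 features); their pooled union has 33 unique
features, a structural identity the test suite verifies.

# Classification and validation

`fitPipeline` chains column subsetting → per-feature standardization (fit
on training data only) → projection onto the one-dimensional Fisher
discriminant → a linear SVM (cost 1, equal class weights) on the projected
score. Standardization is applied because both the discriminant and the
SVM are scale-sensitive; the discriminant direction uses a pseudo-inverse
of the pooled within-class covariance, so duplicated or collinear features
leave the decision function unchanged. For a binary problem the
discriminant has a single component by construction.

Two protocols mirror common practice:

* `evaluateRepeatedKFold`: stratified 10-fold, 3 repeats (30 folds), the
  whole pipeline refit inside every fold; mean ± SD accuracy and macro
  ROC-AUC over folds.
* `evaluateHoldout`: stratified 66/33 split at the image level, per-class
  precision/recall/F1, confusion matrix and macro ROC-AUC on the test
  portion.

Feature selection can run **fold-safe** (pass a selector function, which
is then fit on each fold's training rows — the leakage-free default used
in all shipped evaluations) or **panel-parity** (pass a fixed
`FeatureSubset` computed once, reproducing the common published protocol
in which selection precedes cross-validation). Both are provided because
published pipelines are frequently ambiguous on this point; the package's
own tests include a label-randomization canary that must stay at chance
accuracy under the fold-safe mode.

Macro ROC-AUC averages the one-vs-rest AUCs (midrank ties); for binary
labels it equals the AUC of the decision score.

Grouped (per-donor) splitting is not implemented: the pipeline splits at
the image level, and when several images derive from the same donor the
resulting estimates are optimistic about cross-donor generalization. This
caveat is inherited from the data layout the pipeline targets, which
carries no donor identifiers.

# The phantom generator

`generateImage` renders straight anti-aliased segments with lengths from a
truncated normal and orientations from a von Mises distribution
(concentration \(\kappa\); \(\kappa = 0\) is isotropic), max-blends them
(fibers occlude rather than add), applies a separable Gaussian blur with
reflected edges, adds Gaussian background noise and clips/rounds to 8-bit.
The two presets caricature the two phenotypes:

* `control`: 45 fibers, length 200 ± 50 px, thickness 3.5 px,
  \(\kappa = 8\) — long, coherent, aligned bundles;
* `remodeled`: 260 fibers, length 22 ± 8 px, thickness 2.8 px,
  \(\kappa = 0\) — short, fragmented, isotropic segments;

both at 450 × 450 px, fiber intensity 180, blur 1.2 px, background noise
SD 6 (dim enough that an empty scene fails the low-signal filter, so that
code path is exercised). No quantitative morphometry of real airway
collagen is published to calibrate against, so these are deliberate
caricatures chosen to be separable, not tissue-calibrated models. The
generator does not emulate the SHG point-spread function, polarization
effects, detector noise statistics or tissue background autofluorescence —
so passing phantom tests demonstrates that the pipeline recovers planted
morphological differences, not that it attains any particular accuracy on
real tissue.

Determinism: an image is a pure function of its parameter object
(including its seed); datasets derive per-image seeds from the master seed
and image index, so generation is reproducible image-by-image.

# Numerical and size choices in the shipped checks

The validation suite verifies each texture matrix against brute-force
enumeration on 100 random images up to 8 × 8 (exhaustive at that size),
checks rotation/mirror invariance of the directional averages at 1e-9, and
runs the full pipeline end-to-end on 200 phantom images per class for the
effect condition and 100 per class for the null (identical parameters for
both classes), with chance behavior assessed by repeated k-fold macro AUC
— averaging over 30 folds, which estimates the null AUC far more stably
than a single holdout split. Selector recovery uses planted tables with a
2-pooled-SD class-mean shift, 200 rows, 10 seeds. Smaller rasters
(64–160 px) are used in invariant tests where the property under test does
not depend on image size; the monotonicity-of-separability check
interpolates fiber geometry between the two presets at 128 px and 25
images per class.

# Known limitations

* Features are not scale-invariant: magnification, ROI and window-size
  changes alter them. Images compared by the pipeline must share
  acquisition scale.
* No ROI segmentation, denoising or background subtraction is performed.
* Local binary patterns and Laws' textures are out of scope, as are RBF
  kernels, hyperparameter search, calibration and multiclass problems.
* Image-level splitting overestimates cross-donor generalization (above).
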