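---
title: "Methods: mask-aware texture features and two-reader tumor-edema discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mask-aware texture features and two-reader tumor-edema discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Peritumoral edema and tumor tissue can be hard to delineate on routine MR
images, yet the distinction drives radiotherapy target definition.  Around
a glioblastoma (GBM) the edema is infiltrated by tumor cells; around a
meningioma it is purely vasogenic.  radtex implements a radiomics workflow
for this discrimination task: large numbers of quantitative texture
features are extracted from manually contoured 2D regions of interest
(ROIs) on five MR sequences (FLAIR, ADC, T1W pre/post contrast, T2W), a
penalized regression selects the few features that separate tumor from
edema, and the selected features are evaluated by ROC analysis.  Because
two readers contour independently, selection is run per reader and only
features chosen for *both* are kept.

The package ships a synthetic cohort generator that reproduces the
*statistical* structure of such a study (two tissues, two readers, five
sequences, two disease arms with different kinds of tissue contrast), so
that every stage of the pipeline is testable end to end without patient
data.

## Pipeline overview

1. **ROI input** (`read_roi`, `roi_image`): a float intensity raster plus a
   binary mask plus metadata.  NIfTI slices and a plain CSV raster dialect
   are supported; contours are expected pre-rasterized to binary masks.
   A configurable floor (default 16 in-mask pixels) rejects regions too
   small for texture statistics.  Masks contoured on one sequence are
   replicated onto co-registered sequences with `transfer_mask`; ADC maps
   can be computed voxelwise from b = 0 / b = 1000 s/mm^2 acquisitions with
   `compute_adc` (signals floored at `1e-6 * median(S0)` to avoid
   log-of-zero; the floor is arbitrary but only engages on non-physical
   zero signals).
2. **Normalization** (`normalize_1_99`): optional per-ROI intensity
   compaction to the range between 1% and 99% of the cumulative in-mask
   histogram, then a linear map onto [0, 1].  Each ROI is normalized
   against its own histogram.  Raw-scale analyses are run alongside, so
   every scenario exists in a "none" and a "p1_99" variant.
3. **Quantization** (`quantize`): equal-width binning of the in-mask range
   into `n_levels` gray levels (default 64, configurable 8-256).  The rule
   uses only the in-mask min/max, making all matrix-based features
   invariant under positive affine intensity maps.
4. **Feature extraction** (`extract_features`): 20 first-order features,
   22 GLCM features at 5 distances x 4 angles (440), and 13 GLRLM features
   at 4 angles (52) - 512 named features per ROI.
5. **Selection** (`fit_lasso_logistic`, `consensus_selection`): per-reader
   L1-penalized logistic regression of tissue on z-standardized features,
   penalty chosen by 10-fold cross-validated deviance, then the
   intersection across readers.
6. **Evaluation** (`roc_auc`, `find_perfect_threshold`, `cohens_kappa`,
   `evaluate_scenarios`): univariate ROC with DeLong 95% CIs, a
   multivariable unpenalized refit on the consensus set, single-feature
   perfect-classification thresholds where class ranges are disjoint, and
   inter-rater kappa.

## Feature definitions and conventions

**Percentiles.**  One convention everywhere: linear interpolation between
closest ranks (R's `type = 7`), wrapped in `pctl()` and shared by the
normalization bounds and the percentile features.  Percentile-threshold
reports are sensitive to this choice, which is why it is centralized.

**First-order family.**  Moments are population moments; kurtosis is
non-excess (a normal sample gives values near 3).  Histogram entropy
(bits, `0 log 0 := 0`), energy and uniformity are computed over a 256-bin
equal-width histogram of the in-mask values; under this convention energy
and uniformity coincide (both are the sum of squared bin probabilities)
and both names are emitted for completeness of the reported feature list.
The absolute gradient uses central differences where both neighbors are
in-mask and one-sided differences at the mask boundary, with the Euclidean
magnitude; its mean, variance, skewness and kurtosis are reported.
Coarseness, directionality and contrast follow Tamura-style constructions:
coarseness is the mean best window size (powers of two up to 16) of
mask-aware box-average differences; directionality is the concentration
(sum of squared bin probabilities, 16 orientation bins) of the
gradient-orientation histogram; contrast is `sd / kurtosis^0.25`.  These
three are convention-dependent across the literature; the package
documents its own forms rather than claiming equivalence to any specific
prior implementation.

**GLCM.**  The angle-to-offset convention, in (row, col) with rows growing
downward, is 0 deg = (0, +d), 45 deg = (-d, +d), 90 deg = (-d, 0),
135 deg = (-d, -d).  Ordered pairs are counted only when both endpoints
are inside the mask (the ROIs are irregular, so a rectangle-based matrix
would count tissue outside the contour).  The transpose is added -
regular and transpose matrices summed - giving a symmetric matrix, which
also makes the opposite orientations redundant; the matrix is then
normalized to probabilities.  The 22 features use the standard marginal
constructions (p_x, p_{x+y}, p_{x-y}), logs base 2, `0 log 0 := 0`.  Sum
variance is computed about the sum average (the common modern convention).
IMC2 is `sqrt(1 - exp(-2 (HXY2 - HXY)))` clamped at zero before the square
root.  Both "sum of squares (variance)" and "cluster tendency" are
emitted under distinct names even though their canonical definitions
overlap in parts of the literature, because the reported feature list
names both.  Zero denominators (e.g. correlation of a constant matrix)
flag the feature as undefined - the value is a 0 placeholder and the name
is recorded in the vector's `undefined` attribute; such entries become
`NA` in feature tables and the affected columns are dropped per scenario
before selection.

**GLRLM.**  A run is a maximal collinear segment of in-mask pixels with
one gray level; mask gaps terminate runs.  Diagonal traversals enumerate
all 45/135-degree lines intersecting the raster, clipped to the mask.
The matrix satisfies the conservation identity
`sum_i sum_l l * r(i, l) = n_masked_pixels`, which the test suite asserts
on hundreds of random masked images.  Gray-level and run-length variance
are computed over the run probability distribution `r(i, l) / n_runs`.
Features are computed per angle (not angle-merged), since per-angle
features are what a scenario report names.

## Selection procedure

Within one scenario (disease x normalization x sequence), each reader's
table has one row per ROI.  Features are z-standardized; zero-variance and
undefined-flagged columns are dropped.  `glmnet` fits the binomial-family,
logit-link L1 path, and 10-fold cross-validation with a seeded,
class-stratified fold assignment picks the penalty minimizing CV deviance
("the penalty minimizing the prediction error"; fold count and loss are
package choices, fixed at 10-fold deviance).  Features with nonzero
coefficients at that penalty are that reader's selection; coefficients are
mapped back to the raw feature scale for reporting.  The cross-reader
consensus is the plain intersection - symmetric, idempotent, and
conservative by construction.  An empty intersection with at least one
nonempty per-reader set is a real outcome (`no_agreement`, rendered "NA");
two empty sets give `none_selected`.  Nested cross-validation is
deliberately not used; the cross-reader intersection is the overfitting
control.  Complete separation is legal and expected in strong-signal
scenarios: the L1 path is still defined, and the path-convergence notices
glmnet emits at tiny penalties are muffled because selection only uses the
valid larger-penalty part of the path.

Set-size behavior under the null is worth stating: with 40 observations
and 20 pure-noise features the deviance-minimizing penalty keeps a median
of 0 features, but a minority of seeds admit several noise features - the
CV-minimum rule is not a sparsistency guarantee.  The cross-reader
intersection is what makes the reported consensus robust: two independent
noise selections almost never agree.

## Evaluation

AUC is the Mann-Whitney statistic (ties counted half), oriented so the
reported value is >= 0.5 with the direction recorded (`greater_is_tumor` /
`less_is_tumor`).  Confidence intervals use the DeLong variance method,
clipped to [0, 1]; with all scores tied the AUC is fixed at 0.5 and
flagged degenerate.  ROC rows pool both readers' ROIs (each reader's
reading of a region is one observation).  Where a consensus feature's
class ranges are disjoint, a perfect threshold is reported with the cut at
the midpoint of the two boundary observations - exact midpoints are
reported rather than display-rounded values; otherwise the
accuracy-maximizing midpoint is reported with `perfect = FALSE`, ties
broken toward the smaller cut.  The multivariable model is an unpenalized
logistic refit on the consensus set (relaxed-LASSO-style reporting); with
a single consensus feature its AUC equals the univariate AUC because AUC
is invariant under monotone transforms.  Cohen's kappa uses the standard
observed/expected form with one documented degenerate rule: two constant
raters give kappa 1 when they agree and 0 when they do not.

## The synthetic cohort: what it emulates, and what it does not

Defaults: 17 GBM + 8 meningioma patients, 2 slices per patient, five
sequences, two readers, 48 x 48 rasters with elliptical masks
(semi-axes 10-16 px, ~300-800 px area, sinusoidal boundary jitter), base
intensities at raw-MR-like magnitudes (per-sequence means 500-1200,
within-ROI sd 100), and a per-patient random mean offset (0.3 sd) shared
by both tissues.  Reader B's mask is an erosion or dilation (disc radius
0-2 px) of reader A's on the *same* pixel field - both readers read the
same image - giving Dice overlaps >= 0.8 by construction, the package's
emulation of expert-level agreement.  Both readers label the regions they
contour identically, so tissue-classification kappa is 1, mirroring a
study design in which readers agree on what is tumor and what is edema
and differ only in boundary placement.

The two arms plant different, known contrasts:

* **meningioma** - a first-order contrast: tumor means are shifted by
  1.5 sd relative to edema (direction per sequence: tumor darker on ADC,
  FLAIR, T1W, T2W; brighter on T1W+C), with identical spatial correlation
  in both tissues.  Histogram percentiles and location features are the
  ground-truth discriminators, and the perfect-threshold direction is
  known per sequence.
* **GBM** - a second-order contrast: tumor fields are smoothed white noise
  (correlation length 2.5 px) and edema fields are white noise, with the
  marginal histogram matched *exactly* between tissues by a normal-scores
  transform (in-mask ranks mapped onto the Gaussian quantile grid).  Only
  spatial arrangement differs, so co-occurrence features are the
  ground-truth discriminators and first-order features carry no signal.
  Moment matching alone is insufficient here: a smoothed field has fewer
  effective independent samples, which leaves a detectable finite-sample
  quantile-shape signature; pinning the whole histogram removes it.

Two consequences matter for interpreting pipeline output on this cohort.
First, per-ROI 1-99% normalization erases a pure between-tissue mean
shift, so normalized meningioma scenarios have *no* recoverable signal -
they are expected to end as "None Selected" or "NA", and occasionally as
a spurious small-sample consensus (both readers see nearly the same
pixels, so their chance selections are correlated).  Second, the planted
GBM contrast survives normalization, because quantization and
co-occurrence structure are affine-invariant.

The generator emulates statistical structure only.  It does not simulate
MR physics: no bias fields, no partial-volume effects, no inter-sequence
intensity relationships, no anatomically shaped lesions.  Passing tests on
this cohort demonstrate that the pipeline recovers the kind of signal it
is designed to find, under the study's sample sizes and reader structure;
they do not validate diagnostic performance on real images.

## Numerical and degenerate-input choices

* Constant ROI: normalization returns zeros with a degenerate flag
  (logged, not an error); quantization assigns level 1 everywhere;
  entropy 0, uniformity 1, variance 0; skewness/kurtosis flagged
  undefined.
* Masks too small for an offset (no valid pixel pair at distance d) give
  an empty-flagged GLCM and undefined-flagged features rather than an
  error, so a cohort run can proceed and log.
* Feature vectors never contain silent NaN: every undefined value is a 0
  placeholder plus an explicit flag, surfaced as `NA` in tables.
* All randomness (cohort generation, CV folds, null simulations) flows
  from explicit integer seeds; two runs with the same configuration and
  seed produce byte-identical feature CSVs and reports.  The default
  selection seed is 20181008.
* Problem sizes are chosen for a desk-scale analysis: the default cohort
  (1000 ROIs, 2 normalization modes, 512 features) extracts in a few
  minutes on one CPU, and the oracle-equivalence tests run on hundreds of
  small random images (<= 12 x 12) where brute-force enumeration is exact
  and fast.

## Known limitations

* DICOM input is not implemented (no reader dependency is available to
  the package); NIfTI slices and the CSV dialect cover the same contract.
* Coarseness/directionality/contrast are package conventions; numerical
  comparability with other radiomics toolkits is not claimed for these
  three.  GLCM/GLRLM/moment/percentile features follow the standard
  definitions and are oracle-tested.
* The "~300 parameters" scale of the motivating design corresponds here
  to the full 512-name grid; no attempt is made to match a specific
  historical feature count.
* 2D only; 3D texture volumes, alternative normalizations (mean +/- 3 sd,
  bit-depth compression) and transform-domain preprocessing are out of
  scope.
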