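# radtex

Mask-aware 2D radiomic texture analysis for discriminating brain tumor
from peritumoral edema on multiparametric MRI.

## What this is for

Delineating tumor from surrounding edema drives radiotherapy target
definition, and the two tissues can look alike on routine MR sequences.
radtex implements the radiomics approach to this problem for image
analysts and methodologists: extract a few hundred quantitative texture
features from contoured regions of interest (ROIs) on each sequence
(FLAIR, ADC, T1W, T1W+C, T2W), let a penalized regression find the few
features that separate tumor from edema, and evaluate those features by
ROC analysis.  Two readers contour independently; selection runs per
reader and only features selected for **both** survive, which is the
workflow's guard against small-sample overfitting.

A synthetic cohort generator reproduces the statistical structure of such
a two-reader study (two disease arms with different planted contrasts),
so the entire pipeline is testable without patient data.

## The core quantities

For an ROI quantized to gray levels 1..N_g, the symmetric **gray-level
co-occurrence matrix** holds P(i, j | d, θ): the probability that two
in-mask pixels at offset distance d ∈ {1..5} and orientation
θ ∈ {0°, 45°, 90°, 135°} have levels i and j (regular + transpose
matrices summed).  Twenty-two Haralick-family statistics (contrast,
correlation, entropy, sum/difference statistics, information measures of
correlation, ...) are computed per (d, θ).  The **gray-level run-length
matrix** holds r(i, ℓ), the number of maximal in-mask runs of level i and
length ℓ along θ, with Σ ℓ·r(i, ℓ) equal to the masked pixel count;
thirteen run statistics are computed per angle.  Twenty first-order
features (moments, 256-bin histogram entropy/energy/uniformity,
percentiles under the type-7 convention, Tamura-style descriptors,
absolute-gradient statistics) complete the 512-name feature vector.

Selection fits an L1-penalized logistic regression (binomial family,
logit link) of tissue on z-standardized features per reader, with the
penalty λ chosen by 10-fold cross-validation to minimize deviance, and
intersects the readers' nonzero-coefficient sets.  Evaluation reports the
Mann-Whitney AUC with DeLong 95% CIs per consensus feature, perfect
single-feature thresholds where the class ranges are disjoint, and
Cohen's κ between the readers' tissue classifications.

## Worked example

```r
library(radtex)

# two ROIs with identical marginal histograms but different spatial texture
roi_t <- generate_textured_roi(mean = 800, sd = 100, corr_len = 2.5,
                               marginal = "exact", seed = 42)
roi_e <- generate_textured_roi(mean = 800, sd = 100, corr_len = 0,
                               marginal = "exact", seed = 43)
f_t <- extract_features(roi_t)   # 512 named features
f_e <- extract_features(roi_e)
f_t[["GLCM_Correlation_d1_a000"]]   # 0.937  (smoothed field)
f_e[["GLCM_Correlation_d1_a000"]]   # -0.007 (white noise)
f_t[["HIST_Percentile50"]]          # 800.0  -- identical for both:
f_e[["HIST_Percentile50"]]          # 800.0     the histograms match

# a reduced two-sequence cohort through the full pipeline
spec <- cohort_spec(n_patients = c(GBM = 6L, meningioma = 6L),
                    slices_per_patient = 1L, sequences = c("FLAIR", "T2W"))
report <- run_full(generate_cohort(spec), normalization = "none",
                   distances = 1:2, angles = c(0, 90))
render_report(report)[, c("Disease", "Sequence", "MostUseful", "AUC")]
#>      Disease Sequence MostUseful                               AUC
#> 1        GBM    FLAIR ...; GLCM_Correlation_d1_a000; ...       PC
#> 2 meningioma    FLAIR HIST_Percentile50                        PC
#> 3        GBM      T2W ...; GLCM_Correlation_d1_a090; ...       PC
#> 4 meningioma      T2W HIST_Percentile50                        PC
report$kappa
#> [1] 1
```

The report reads like the study table it mirrors: in the GBM arm the
consensus discriminators are co-occurrence (GLCM) features — the planted
contrast there is purely spatial — while in the meningioma arm they are
histogram features tracking the planted intensity shift; "PC" marks
scenarios where a single-feature threshold classifies every ROI
correctly, and κ = 1 reflects that both readers label the same contoured
regions.

## The analysis workflow

The numbered scripts under `analysis/` run the full default cohort
(17 GBM + 8 meningioma patients, 2 slices, 5 sequences, 2 readers, raw +
normalized) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # cohort + ground-truth ledger
Rscript analysis/02_extract.R     # 2000 x 512 feature table
Rscript analysis/03_select.R      # per-scenario LASSO + consensus
Rscript analysis/04_evaluate.R    # ROC/threshold/kappa report
```

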