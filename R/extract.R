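# Per-ROI feature extraction: first-order + GLCM block + GLRLM block.

#' Extract the full feature vector of one ROI
#'
#' Runs the three feature families on an ROI: first-order histogram features
#' on the (optionally normalized) intensities, then gray-level quantization
#' ([quantize()]) followed by the GLCM block over the (d, theta) grid and
#' the GLRLM block over the angle grid.  With the defaults this yields
#' 20 + 440 + 52 = 512 named features.
#'
#' @param roi an `roi_image`.
#' @param normalization `"none"` (raw intensities) or `"p1_99"`
#'   (1%-99% normalization applied first, see [normalize_1_99()]).
#' @param n_levels gray levels for quantization (default 64).
#' @param distances GLCM distances (default 1:5).
#' @param angles GLCM/GLRLM orientations (default 0, 45, 90, 135).
#' @param n_bins histogram bins for the first-order family (default 256).
#' @return a `feature_vector`; undefined-flagged entries are listed by
#'   [feature_undefined()].
#' @export
extract_features <- function(roi, normalization = c("none", "p1_99"),
                             n_levels = 64L, distances = 1:5,
                             angles = .ANGLES, n_bins = 256L) {
  normalization <- match.arg(normalization)
  if (normalization == "p1_99") roi <- normalize_1_99(roi)
  q <- quantize(roi, n_levels = n_levels)
  fv_concat(histogram_features(roi, n_bins = n_bins),
            glcm_feature_block(q, distances = distances, angles = angles),
            glrlm_feature_block(q, angles = angles))
}
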