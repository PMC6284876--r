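# Intensity normalization and gray-level quantization.

#' 1%-99% cumulative-histogram normalization
#'
#' Compacts the intensity range of a masked ROI to the gray-scale range lying
#' between 1% and 99% of its cumulative histogram: the 1st and 99th
#' percentiles of the in-mask intensities (shared percentile convention,
#' [pctl()]) are taken as bounds, in-mask values are clipped to them and then
#' mapped linearly onto `[0, 1]`.  Pixels outside the mask are left
#' untouched.  Each ROI is normalized against its own histogram, so different
#' ROIs generally use different bounds.
#'
#' A constant (or effectively constant, p1 == p99) ROI cannot be rescaled;
#' it is returned with all in-mask values 0 and a `degenerate` flag instead
#' of an error, so that cohort runs can log and continue.
#'
#' @param roi an `roi_image`.
#' @return an `roi_image` with `normalization = "p1_99"`, an attribute-free
#'   `degenerate` field (TRUE/FALSE), and in-mask values in `[0, 1]`.
#' @export
normalize_1_99 <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  v <- roi_values(roi)
  out <- roi
  out$normalization <- "p1_99"
  if (length(unique(v)) < 2L) {
    out$pixels[out$mask] <- 0
    out$degenerate <- TRUE
    return(out)
  }
  b <- pctl(v, c(0.01, 0.99))
  p1 <- b[1L]; p99 <- b[2L]
  if (p99 <= p1) {
    out$pixels[out$mask] <- 0
    out$degenerate <- TRUE
    return(out)
  }
  out$pixels[out$mask] <- (pmin(pmax(v, p1), p99) - p1) / (p99 - p1)
  out$degenerate <- FALSE
  out
}

#' Quantize a masked ROI to discrete gray levels
#'
#' Equal-width binning of the in-mask intensity range into `n_levels` bins:
#' `level = 1 + floor(n_levels * (v - min) / (max - min))`, with the maximum
#' value assigned level `n_levels`.  Pixels outside the mask are level 0.
#' The rule depends only on the in-mask min/max, so it is invariant under
#' positive affine rescaling of the intensities; matrix-based features
#' computed from the levels inherit that invariance.
#'
#' @param roi an `roi_image`.
#' @param n_levels number of gray levels (2-256; default 64).
#' @return object of class `quantized_roi`: `levels` (integer matrix, 0
#'   outside mask), `n_levels`, `mask`, and `rule` (mode, bounds, degenerate
#'   flag).
#' @export
quantize <- function(roi, n_levels = 64L) {
  stopifnot(inherits(roi, "roi_image"))
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L || n_levels > 256L) stop("n_levels must be in 2..256")
  v <- roi_values(roi)
  lo <- min(v); hi <- max(v)
  lev <- matrix(0L, nrow(roi$pixels), ncol(roi$pixels))
  degenerate <- hi <= lo
  if (degenerate) {
    lev[roi$mask] <- 1L
  } else {
    l <- 1L + as.integer(floor(n_levels * (v - lo) / (hi - lo)))
    l[l > n_levels] <- n_levels
    lev[roi$mask] <- l
  }
  structure(list(levels = lev, n_levels = n_levels, mask = roi$mask,
                 rule = list(mode = if (roi$normalization == "none")
                   "raw_range" else "normalized",
                   lower_bound = lo, upper_bound = hi,
                   degenerate = degenerate)),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi %dx%d, %d levels, %d masked px%s>\n",
              nrow(x$levels), ncol(x$levels), x$n_levels, sum(x$mask),
              if (x$rule$degenerate) ", degenerate" else ""))
  invisible(x)
}
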