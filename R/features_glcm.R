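# Second-order features: gray-level co-occurrence matrices and the 22
# Haralick-family statistics computed from them.
#
# Angle-to-offset convention, in (row, col) with rows increasing downward:
#     0 degrees -> ( 0, +d)      45 degrees -> (-d, +d)
#    90 degrees -> (-d,  0)     135 degrees -> (-d, -d)
# Ordered pairs are counted only when both endpoints are inside the mask;
# the transpose is added (regular + transpose GLCM summed, giving a
# symmetric matrix) and the result normalized to probabilities, so the
# opposite orientations (theta + 180 degrees) are covered by symmetry.

.glcm_offset <- function(d, theta) {
  switch(as.character(as.integer(theta)),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix of a quantized ROI
#'
#' Counts every ordered in-mask pixel pair at offset (`d`, `theta`), adds the
#' transpose, and normalizes to a symmetric probability matrix
#' `p(i, j | d, theta)`.  A mask too small to contain any pair at the given
#' offset yields an empty-flagged matrix; downstream features are then
#' flagged undefined rather than computed.
#'
#' @param qroi a `quantized_roi` from [quantize()].
#' @param d offset distance in pixels (1-5 in the standard grid).
#' @param theta orientation in degrees: 0, 45, 90 or 135.
#' @return object of class `glcm`: `p` (n_levels x n_levels probabilities),
#'   `d`, `theta`, `n_pairs` (ordered pairs counted before symmetrization),
#'   `empty`.
#' @export
compute_glcm <- function(qroi, d, theta) {
  stopifnot(inherits(qroi, "quantized_roi"))
  d <- as.integer(d)
  if (d < 1L) stop("d must be a positive integer")
  off <- .glcm_offset(d, theta)
  lev <- qroi$levels
  mk <- qroi$mask
  ng <- qroi$n_levels
  nr <- nrow(lev); nc <- ncol(lev)
  dr <- off[1L]; dc <- off[2L]

  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  counts <- matrix(0, ng, ng)
  n_pairs <- 0L
  if (r1 <= r2 && c1 <= c2) {
    a_m <- mk[r1:r2, c1:c2, drop = FALSE]
    b_m <- mk[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
    valid <- a_m & b_m
    if (any(valid)) {
      i <- lev[r1:r2, c1:c2, drop = FALSE][valid]
      j <- lev[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE][valid]
      counts <- matrix(tabulate(i + (j - 1L) * ng, nbins = ng * ng), ng, ng)
      n_pairs <- sum(valid)
    }
  }
  if (n_pairs == 0L) {
    return(structure(list(p = counts, d = d, theta = as.integer(theta),
                          n_pairs = 0L, empty = TRUE), class = "glcm"))
  }
  sym <- counts + t(counts)
  structure(list(p = sym / sum(sym), d = d, theta = as.integer(theta),
                 n_pairs = n_pairs, empty = FALSE), class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm %dx%d, d=%d theta=%d, %d pairs%s>\n",
              nrow(x$p), ncol(x$p), x$d, x$theta, x$n_pairs,
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

# cached index matrices keyed by matrix size
.glcm_cache <- new.env(parent = emptyenv())
.glcm_idx <- function(ng) {
  key <- as.character(ng)
  got <- .glcm_cache[[key]]
  if (is.null(got)) {
    got <- list(I = matrix(rep(seq_len(ng), ng), ng, ng),
                J = matrix(rep(seq_len(ng), each = ng), ng, ng))
    .glcm_cache[[key]] <- got
  }
  got
}

#' Haralick-family features of a co-occurrence matrix
#'
#' The 22 second-order statistics over a symmetric GLCM with marginals
#' `p_x`, `p_y`, `p_{x+y}`, `p_{x-y}`: autocorrelation, contrast (inertia),
#' correlation, cluster prominence/shade/tendency, dissimilarity, angular
#' second moment (energy), entropy, homogeneity (inverse difference moment),
#' inverse variance, maximum probability, sum of squares (variance), sum
#' average/variance/entropy, difference variance/entropy, the two
#' information measures of correlation (IMC1, IMC2), and the normalized
#' inverse-difference forms (IDN, IDMN).  Logs are base 2 with
#' `0 log 0 := 0`; `IMC2 = sqrt(1 - exp(-2 (HXY2 - HXY)))` clamped at 0.
#' Zero denominators (constant matrices) flag the affected feature as
#' undefined; an empty matrix flags all of them.
#'
#' @param g a `glcm` from [compute_glcm()].
#' @return a `feature_vector` of 22 `GLCM_*` features.
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  nms <- paste0("GLCM_", c("Autocorrelation", "Contrast", "Correlation",
                           "ClusterProminence", "ClusterShade",
                           "ClusterTendency", "Dissimilarity", "Energy",
                           "Entropy", "Homogeneity", "InverseVariance",
                           "MaxProbability", "SumOfSquares", "SumAverage",
                           "SumVariance", "SumEntropy", "DiffVariance",
                           "DiffEntropy", "IMC1", "IMC2", "IDN", "IDMN"))
  if (g$empty) {
    return(fv(stats::setNames(rep(0, length(nms)), nms), undefined = nms))
  }
  p <- g$p
  ng <- nrow(p)
  ix <- .glcm_idx(ng)
  I <- ix$I; J <- ix$J
  undefined <- character()

  px <- rowSums(p)                     # == colSums by symmetry
  iv <- seq_len(ng)
  mu <- sum(iv * px)
  sig2 <- sum((iv - mu)^2 * px)
  sig <- sqrt(sig2)

  ipj <- sum(I * J * p)
  dif <- I - J
  contrast <- sum(dif^2 * p)
  if (sig2 > 0) {
    correlation <- (ipj - mu * mu) / sig2
  } else {
    correlation <- 0
    undefined <- c(undefined, "GLCM_Correlation")
  }
  dev <- I + J - 2 * mu
  adif <- abs(dif)

  # sum / difference marginals
  pplus <- as.vector(rowsum(as.vector(p), group = as.vector(I + J)))
  kplus <- seq.int(2L, 2L * ng)
  pminus <- as.vector(rowsum(as.vector(p), group = as.vector(adif)))
  kminus <- seq.int(0L, ng - 1L)
  sum_avg <- sum(kplus * pplus)
  sum_var <- sum((kplus - sum_avg)^2 * pplus)
  diff_avg <- sum(kminus * pminus)
  diff_var <- sum((kminus - diff_avg)^2 * pminus)

  entropy <- .plog2(p)
  pxpy <- outer(px, px)
  nzj <- pxpy > 0
  hxy1 <- -sum(p[nzj] * log2(pxpy[nzj]))
  hxy2 <- .plog2(pxpy)
  hx <- .plog2(px)
  if (hx > 0) {
    imc1 <- (entropy - hxy1) / hx       # max(HX, HY) = HX by symmetry
  } else {
    imc1 <- 0
    undefined <- c(undefined, "GLCM_IMC1")
  }
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  offd <- dif != 0
  vals <- c(
    GLCM_Autocorrelation = ipj,
    GLCM_Contrast = contrast,
    GLCM_Correlation = correlation,
    GLCM_ClusterProminence = sum(dev^4 * p),
    GLCM_ClusterShade = sum(dev^3 * p),
    GLCM_ClusterTendency = sum(dev^2 * p),
    GLCM_Dissimilarity = sum(adif * p),
    GLCM_Energy = sum(p^2),
    GLCM_Entropy = entropy,
    GLCM_Homogeneity = sum(p / (1 + dif^2)),
    GLCM_InverseVariance = sum(p[offd] / dif[offd]^2),
    GLCM_MaxProbability = max(p),
    GLCM_SumOfSquares = sum((I - mu)^2 * p),
    GLCM_SumAverage = sum_avg,
    GLCM_SumVariance = sum_var,
    GLCM_SumEntropy = .plog2(pplus),
    GLCM_DiffVariance = diff_var,
    GLCM_DiffEntropy = .plog2(pminus),
    GLCM_IMC1 = imc1,
    GLCM_IMC2 = imc2,
    GLCM_IDN = sum(p / (1 + adif / ng)),
    GLCM_IDMN = sum(p / (1 + dif^2 / ng^2))
  )
  stopifnot(identical(names(vals), nms))
  fv(vals, undefined = undefined)
}

#' Full GLCM feature block over the (d, theta) grid
#'
#' Applies [compute_glcm()] + [glcm_features()] over every combination of
#' the distance and angle grids (default d = 1..5, theta = 0/45/90/135:
#' 20 matrices, 440 uniquely named features) and concatenates the results
#' with `_dK_aAAA` suffixes, e.g. `GLCM_Correlation_d1_a090`.
#'
#' @param qroi a `quantized_roi`.
#' @param distances integer distances (default 1:5).
#' @param angles orientations in degrees (default 0, 45, 90, 135).
#' @return a `feature_vector` of `22 * length(distances) * length(angles)`
#'   features; per-(d, theta) undefined flags are propagated.
#' @export
glcm_feature_block <- function(qroi, distances = 1:5, angles = .ANGLES) {
  blocks <- vector("list", length(distances) * length(angles))
  k <- 0L
  for (d in distances) {
    for (th in angles) {
      k <- k + 1L
      f <- glcm_features(compute_glcm(qroi, d, th))
      suf <- paste0("_", .dist_tag(d), "_", .angle_tag(th))
      nm <- paste0(names(f), suf)
      und <- feature_undefined(f)
      if (length(und)) und <- paste0(und, suf)
      blocks[[k]] <- fv(stats::setNames(as.numeric(f), nm), undefined = und)
    }
  }
  do.call(fv_concat, blocks)
}
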