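# First-order features: statistics of the in-mask intensity histogram plus
# absolute-gradient statistics and the Tamura-style coarseness /
# directionality / contrast descriptors.

#' First-order (histogram) features of a masked ROI
#'
#' Computes, over in-mask pixels only:
#' \itemize{
#'   \item moments: mean, population variance, standard deviation, skewness
#'     (third standardized moment) and kurtosis (fourth standardized moment,
#'     non-excess: a normal sample is near 3);
#'   \item histogram descriptors over an `n_bins` equal-width histogram of
#'     the in-mask values: energy and uniformity (both the sum of squared
#'     bin probabilities under this convention, emitted under both names)
#'     and entropy in bits (`0 log 0 := 0`);
#'   \item percentiles 1/10/50/90/99 under the shared convention ([pctl()]);
#'   \item Tamura-style coarseness, directionality, and contrast
#'     (contrast = sd / kurtosis^0.25);
#'   \item absolute gradient: mean, population variance, skewness and
#'     kurtosis of the finite-difference gradient magnitude, central
#'     differences where both neighbors are in-mask and one-sided at the
#'     mask boundary.
#' }
#' Undefined cases (zero variance, degenerate gradients) are flagged, see
#' [feature_undefined()].
#'
#' @param roi an `roi_image`.
#' @param n_bins histogram bins for entropy/energy/uniformity (default 256).
#' @return a `feature_vector` of 20 `HIST_*` features.
#' @export
histogram_features <- function(roi, n_bins = 256L) {
  stopifnot(inherits(roi, "roi_image"))
  v <- roi_values(roi)
  n <- length(v)
  undefined <- character()

  m <- mean(v)
  m2 <- mean((v - m)^2)           # population variance
  s <- sqrt(m2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2
  } else {
    skew <- kurt <- 0
    undefined <- c(undefined, "HIST_Skewness", "HIST_Kurtosis")
  }

  # histogram probabilities over the in-mask range
  rng <- range(v)
  if (rng[2L] > rng[1L]) {
    br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = n_bins)
  } else {
    cnt <- n
  }
  p <- cnt / n
  energy <- sum(p^2)
  entropy <- .plog2(p)

  pcts <- pctl(v, c(0.01, 0.10, 0.50, 0.90, 0.99))

  tam <- .tamura(roi)
  if (kurt > 0) {
    tam_contrast <- s / kurt^0.25
  } else {
    tam_contrast <- 0
    undefined <- c(undefined, "HIST_Contrast")
  }

  g <- .abs_gradient(roi)
  if (length(g) >= 2L) {
    gm <- mean(g)
    g2 <- mean((g - gm)^2)
    if (g2 > 0) {
      gskew <- mean((g - gm)^3) / g2^1.5
      gkurt <- mean((g - gm)^4) / g2^2
    } else {
      gskew <- gkurt <- 0
      undefined <- c(undefined, "HIST_AbsGradSkewness", "HIST_AbsGradKurtosis")
    }
  } else {
    gm <- g2 <- gskew <- gkurt <- 0
    undefined <- c(undefined, "HIST_AbsGradMean", "HIST_AbsGradVariance",
                   "HIST_AbsGradSkewness", "HIST_AbsGradKurtosis")
  }

  fv(c(HIST_Mean = m, HIST_Variance = m2, HIST_SD = s,
       HIST_Skewness = skew, HIST_Kurtosis = kurt,
       HIST_Energy = energy, HIST_Entropy = entropy, HIST_Uniformity = energy,
       HIST_Coarseness = tam$coarseness,
       HIST_Directionality = tam$directionality,
       HIST_Contrast = tam_contrast,
       HIST_Percentile1 = pcts[1L], HIST_Percentile10 = pcts[2L],
       HIST_Percentile50 = pcts[3L], HIST_Percentile90 = pcts[4L],
       HIST_Percentile99 = pcts[5L],
       HIST_AbsGradMean = gm, HIST_AbsGradVariance = g2,
       HIST_AbsGradSkewness = gskew, HIST_AbsGradKurtosis = gkurt),
     undefined = undefined)
}

# gradient magnitude over in-mask pixels; central difference where both
# neighbors are in-mask, one-sided where only one is, component dropped
# where neither is.  Pixels with neither component defined are excluded.
.abs_gradient <- function(roi) {
  px <- roi$pixels
  mk <- roi$mask
  nr <- nrow(px); nc <- ncol(px)
  val <- px
  val[!mk] <- NA_real_

  comp <- function(along) {
    # along = 1 rows (vertical gy), 2 cols (horizontal gx)
    lo <- hi <- matrix(NA_real_, nr, nc)
    if (along == 1L) {
      hi[-nr, ] <- val[-1L, ]; lo[-1L, ] <- val[-nr, ]
    } else {
      hi[, -nc] <- val[, -1L]; lo[, -1L] <- val[, -nc]
    }
    g <- (hi - lo) / 2               # central
    one_hi <- is.na(lo) & !is.na(hi) # one-sided forward
    one_lo <- !is.na(lo) & is.na(hi) # one-sided backward
    g[one_hi] <- (hi - val)[one_hi]
    g[one_lo] <- (val - lo)[one_lo]
    g
  }
  gy <- comp(1L); gx <- comp(2L)
  gy[is.na(gy) & !is.na(gx)] <- 0
  gx[is.na(gx) & !is.na(gy)] <- 0
  mag <- sqrt(gx^2 + gy^2)
  mag[mk & !is.na(mag)]
}

# Tamura-style coarseness and directionality, mask-aware.
#
# Coarseness: classic best-scale construction on box averages of side 2^k
# (k up to 4, limited by the mask bounding box); per-pixel the scale with the
# largest horizontal/vertical average difference wins, coarseness is the mean
# winning window size.  Averages count only in-mask pixels.
#
# Directionality: concentration of the gradient-orientation histogram
# (16 bins over [0, pi)), sum of squared bin probabilities: 1/16 for
# orientation-free texture, 1 for a single dominant orientation.  This is a
# simplified concentration index; the package documents it as its own
# convention since first-order directionality has no single standard form.
.tamura <- function(roi) {
  px <- roi$pixels
  mk <- roi$mask
  rr <- range(which(rowSums(mk) > 0)); cc <- range(which(colSums(mk) > 0))
  sub <- px[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]
  smk <- mk[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]
  nr <- nrow(sub); nc <- ncol(sub)
  kmax <- max(1L, min(4L, floor(log2(min(nr, nc) / 2))))

  vals <- sub; vals[!smk] <- 0
  cnts <- smk + 0
  # summed-area tables with a zero border row/col
  sat <- function(m) {
    s <- rbind(0, cbind(0, m))
    t(apply(apply(s, 2L, cumsum), 1L, cumsum))
  }
  Sv <- sat(vals); Sc <- sat(cnts)
  box <- function(S, r1, r2, c1, c2) {
    S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
      S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
  }

  idx <- which(smk, arr.ind = TRUE)
  best_e <- rep(-Inf, nrow(idx))
  best_k <- rep(1L, nrow(idx))
  for (k in seq_len(kmax)) {
    h <- 2L^(k - 1L)              # half-window
    avg_at <- function(r, c) {
      r1 <- pmax(1L, r - h); r2 <- pmin(nr, r + h - 1L)
      c1 <- pmax(1L, c - h); c2 <- pmin(nc, c + h - 1L)
      n <- box(Sc, r1, r2, c1, c2)
      v <- box(Sv, r1, r2, c1, c2)
      ifelse(n > 0, v / n, NA_real_)
    }
    r <- idx[, 1L]; c <- idx[, 2L]
    eh <- abs(avg_at(r, pmin(nc, c + h)) - avg_at(r, pmax(1L, c - h)))
    ev <- abs(avg_at(pmin(nr, r + h), c) - avg_at(pmax(1L, r - h), c))
    e <- pmax(eh, ev, na.rm = TRUE)
    e[is.na(e)] <- -Inf
    upd <- e > best_e
    best_e[upd] <- e[upd]
    best_k[upd] <- k
  }
  coarseness <- mean(2^best_k)

  # orientation histogram of in-mask gradients
  val <- px; val[!mk] <- NA_real_
  gx <- gy <- matrix(NA_real_, nrow(px), ncol(px))
  gx[, -ncol(px)] <- val[, -1L] - val[, -ncol(px)]
  gy[-nrow(px), ] <- val[-1L, ] - val[-nrow(px), ]
  ok <- mk & !is.na(gx) & !is.na(gy) & (gx != 0 | gy != 0)
  if (sum(ok) >= 2L) {
    ang <- atan2(gy[ok], gx[ok]) %% pi
    bins <- tabulate(pmin(16L, 1L + floor(ang / pi * 16)), nbins = 16L)
    pb <- bins / sum(bins)
    directionality <- sum(pb^2)
  } else {
    directionality <- 1 / 16
  }
  list(coarseness = coarseness, directionality = directionality)
}
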