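# Higher-order features: gray-level run-length matrices at four angles and
# the 13 run-emphasis statistics computed from them.
#
# A run is a maximal collinear segment of in-mask pixels sharing one gray
# level; a mask gap terminates a run.  Runs are direction-symmetric, so one
# traversal per angle suffices:
#     0 degrees: along rows          90 degrees: along columns
#    45 degrees: anti-diagonals      135 degrees: main diagonals

#' Gray-level run-length matrix of a quantized ROI
#'
#' @param qroi a `quantized_roi` from [quantize()].
#' @param theta run angle in degrees: 0, 45, 90 or 135.
#' @return object of class `glrlm`: `r` (n_levels x L_max integer counts of
#'   maximal runs, trimmed to the longest occupied run length), `theta`,
#'   `n_runs`, `n_pixels` (in-mask pixel count).  Satisfies the conservation
#'   identity `sum_i sum_l l * r(i, l) == n_pixels`.
#' @export
compute_glrlm <- function(qroi, theta) {
  stopifnot(inherits(qroi, "quantized_roi"))
  theta <- as.integer(theta)
  if (!theta %in% .ANGLES) stop("theta must be one of 0, 45, 90, 135")
  lev <- qroi$levels          # 0 outside the mask, so gaps break runs
  ng <- qroi$n_levels
  n_pixels <- sum(qroi$mask)
  if (n_pixels == 0L) stop("empty mask")

  lines <- switch(as.character(theta),
    "0"   = split(lev, row(lev)),
    "90"  = split(lev, col(lev)),
    # within a constant row+col (anti-diagonal) or col-row (main diagonal),
    # column-major order traverses the line monotonically
    "45"  = split(lev, row(lev) + col(lev)),
    "135" = split(lev, col(lev) - row(lev)))

  vals <- integer(0); lens <- integer(0)
  for (ln in lines) {
    r <- rle(as.integer(ln))
    keep <- r$values > 0L
    if (any(keep)) {
      vals <- c(vals, r$values[keep])
      lens <- c(lens, r$lengths[keep])
    }
  }
  lmax <- max(lens)
  rmat <- matrix(tabulate(vals + (lens - 1L) * ng, nbins = ng * lmax),
                 ng, lmax)
  structure(list(r = rmat, theta = theta, n_runs = sum(rmat),
                 n_pixels = n_pixels), class = "glrlm")
}

#' @export
print.glrlm <- function(x, ...) {
  cat(sprintf("<glrlm %dx%d, theta=%d, %d runs over %d px>\n",
              nrow(x$r), ncol(x$r), x$theta, x$n_runs, x$n_pixels))
  invisible(x)
}

#' Run-length features of a GLRLM
#'
#' The 13 standard statistics: short/long-run emphasis (SRE/LRE), gray-level
#' and run-length non-uniformity (GLN/RLN), run percentage (runs per masked
#' pixel), low/high gray-level run emphasis (LGLRE/HGLRE), the four joint
#' emphases (SRLGLE, SRHGLE, LRLGLE, LRHGLE), and gray-level / run-length
#' variance (GLV/RLV) computed over the run probability distribution
#' `p(i, l) = r(i, l) / n_runs`.
#'
#' @param rlm a `glrlm` from [compute_glrlm()].
#' @return a `feature_vector` of 13 `GLRLM_*` features.
#' @export
glrlm_features <- function(rlm) {
  stopifnot(inherits(rlm, "glrlm"))
  nms <- paste0("GLRLM_", c("SRE", "LRE", "GLN", "RLN", "RunPercentage",
                            "LGLRE", "HGLRE", "SRLGLE", "SRHGLE", "LRLGLE",
                            "LRHGLE", "GLV", "RLV"))
  nr <- rlm$n_runs
  if (nr == 0L) {
    return(fv(stats::setNames(rep(0, length(nms)), nms), undefined = nms))
  }
  r <- rlm$r
  ng <- nrow(r); lmax <- ncol(r)
  i2 <- matrix(rep(seq_len(ng)^2, lmax), ng, lmax)
  l2 <- matrix(rep(seq_len(lmax)^2, each = ng), ng, lmax)
  p <- r / nr
  pi_ <- rowSums(p); pl <- colSums(p)
  mu_i <- sum(seq_len(ng) * pi_)
  mu_l <- sum(seq_len(lmax) * pl)
  vals <- c(
    GLRLM_SRE = sum(r / l2) / nr,
    GLRLM_LRE = sum(r * l2) / nr,
    GLRLM_GLN = sum(rowSums(r)^2) / nr,
    GLRLM_RLN = sum(colSums(r)^2) / nr,
    GLRLM_RunPercentage = nr / rlm$n_pixels,
    GLRLM_LGLRE = sum(r / i2) / nr,
    GLRLM_HGLRE = sum(r * i2) / nr,
    GLRLM_SRLGLE = sum(r / (i2 * l2)) / nr,
    GLRLM_SRHGLE = sum(r * i2 / l2) / nr,
    GLRLM_LRLGLE = sum(r * l2 / i2) / nr,
    GLRLM_LRHGLE = sum(r * i2 * l2) / nr,
    GLRLM_GLV = sum((seq_len(ng) - mu_i)^2 * pi_),
    GLRLM_RLV = sum((seq_len(lmax) - mu_l)^2 * pl)
  )
  stopifnot(identical(names(vals), nms))
  fv(vals)
}

#' Full GLRLM feature block over the angle grid
#'
#' [compute_glrlm()] + [glrlm_features()] at each angle (default all four:
#' 52 named features), concatenated with `_aAAA` suffixes, e.g.
#' `GLRLM_GLN_a000`.
#'
#' @param qroi a `quantized_roi`.
#' @param angles orientations in degrees (default 0, 45, 90, 135).
#' @return a `feature_vector` of `13 * length(angles)` features.
#' @export
glrlm_feature_block <- function(qroi, angles = .ANGLES) {
  blocks <- lapply(angles, function(th) {
    f <- glrlm_features(compute_glrlm(qroi, th))
    suf <- paste0("_", .angle_tag(th))
    und <- feature_undefined(f)
    if (length(und)) und <- paste0(und, suf)
    fv(stats::setNames(as.numeric(f), paste0(names(f), suf)),
       undefined = und)
  })
  do.call(fv_concat, blocks)
}
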