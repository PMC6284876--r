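# Synthetic two-tissue, two-reader, multi-sequence cohort generator.
#
# Emulates the study structure: per patient and slice, one tumor and one
# edema ROI contoured once and replicated across five MR sequences; two
# readers whose masks differ by small boundary erosion/dilation; two disease
# arms with different planted contrasts.  In the meningioma arm the tissues
# differ in their first-order intensity distribution (a mean shift at equal
# texture), so histogram features discriminate; in the GBM arm the tissues
# differ in spatial correlation length at exactly matched in-mask mean/sd,
# so only second-order (co-occurrence) structure discriminates.

#' Cohort specification
#'
#' Defaults emulate the enrolled study population: 17 GBM and 8 meningioma
#' patients, 2 slices each, the five MR sequences, two readers.
#'
#' @param n_patients named vector: patients per disease arm.
#' @param slices_per_patient slices (ROI pairs per sequence) per patient.
#' @param raster ROI raster size in pixels.
#' @param axes_range ellipse semi-axis range (pixels) for ROI masks.
#' @param sequences sequences to emit.
#' @param base_mean named per-sequence edema mean intensity (arbitrary MR
#'   units, chosen at realistic raw magnitudes so raw-scale thresholds look
#'   like scanner values).
#' @param noise_sd within-ROI intensity standard deviation.
#' @param first_order_shift meningioma tumor-vs-edema mean shift in units of
#'   `noise_sd` (default 1.5: a strong but not degenerate separation).
#' @param shift_sign named per-sequence sign of the meningioma shift
#'   (-1: tumor darker, so the perfect rule has direction `<`).
#' @param texture_corr_len named per-tissue spatial correlation length
#'   (pixels) for the GBM arm; defaults tumor 2.5, edema 0 (white noise).
#' @param menin_corr_len shared correlation length for both meningioma
#'   tissues (texture matched across tissues in that arm).
#' @param patient_jitter_sd per-patient random mean offset (units of
#'   `noise_sd`), applied equally to both tissues.
#' @param reader_perturbation integer range of the erosion/dilation radius
#'   (pixels) used to derive reader B's mask from reader A's.
#' @param seed cohort seed; fixing it makes the cohort bit-reproducible.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = c(GBM = 17L, meningioma = 8L),
                        slices_per_patient = 2L,
                        raster = c(48L, 48L),
                        axes_range = c(10, 16),
                        sequences = .SEQUENCES,
                        base_mean = c(FLAIR = 800, ADC = 1200, T1W = 500,
                                      T1W_C = 700, T2W = 900),
                        noise_sd = 100,
                        first_order_shift = 1.5,
                        shift_sign = c(FLAIR = -1, ADC = -1, T1W = -1,
                                       T1W_C = 1, T2W = -1),
                        texture_corr_len = c(tumor = 2.5, edema = 0),
                        menin_corr_len = 1,
                        patient_jitter_sd = 0.3,
                        reader_perturbation = c(0L, 2L),
                        seed = 20181008L) {
  stopifnot(all(n_patients > 0), slices_per_patient > 0,
            all(raster >= 24), axes_range[1L] > 2,
            axes_range[2L] >= axes_range[1L],
            noise_sd > 0, all(texture_corr_len >= 0), menin_corr_len >= 0,
            reader_perturbation[1L] >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate one textured elliptical ROI
#'
#' A stationary correlated Gaussian field: white noise convolved with an
#' isotropic Gaussian kernel of scale `corr_len` (a separable band-matrix
#' convolution), then linearly rescaled so the in-mask sample mean and sd
#' match the targets exactly.  `corr_len = 0` gives white noise.  The mask
#' is an ellipse with a small sinusoidal boundary jitter.
#'
#' @param mean,sd target in-mask mean and standard deviation.
#' @param corr_len correlation length in pixels (>= 0); the 3-sigma kernel
#'   radius must fit inside the raster.
#' @param shape raster size `c(rows, cols)`.
#' @param axes ellipse semi-axes `c(a, b)` in pixels.
#' @param meta metadata list for the resulting ROI.
#' @param mask optional precomputed mask (overrides the ellipse).
#' @param marginal `"moment"` (default): linear rescale so the in-mask
#'   sample mean/sd equal the targets; `"exact"`: normal-scores transform
#'   mapping the in-mask ranks onto the Gaussian quantiles
#'   `mean + sd * qnorm(ppoints(n))`, which pins the whole marginal
#'   histogram (not just two moments) while preserving the spatial rank
#'   structure.  Fields that must differ only in spatial correlation, never
#'   in their intensity distribution, use `"exact"`.
#' @param seed optional seed (`NULL` leaves the RNG stream alone so callers
#'   can manage determinism at cohort level).
#' @return an `roi_image`.
#' @export
generate_textured_roi <- function(mean, sd, corr_len, shape = c(48L, 48L),
                                  axes = c(14, 11), meta = list(),
                                  mask = NULL,
                                  marginal = c("moment", "exact"),
                                  seed = NULL) {
  marginal <- match.arg(marginal)
  if (!is.null(seed)) set.seed(seed)
  nr <- shape[1L]; nc <- shape[2L]
  if (corr_len > 0 && 6 * corr_len >= min(nr, nc)) {
    stop("smoothing kernel larger than the raster")
  }
  if (is.null(mask)) mask <- .ellipse_mask(nr, nc, axes)
  field <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len > 0) {
    kr <- .gauss_band(nr, corr_len)
    kc <- .gauss_band(nc, corr_len)
    field <- kr %*% field %*% t(kc)
  }
  v <- field[mask]
  s <- stats::sd(v)
  if (s == 0) stop("degenerate field")
  pixels <- mean + (field - base::mean(v)) * (sd / s)
  if (marginal == "exact") {
    n <- length(v)
    q <- mean + sd * stats::qnorm(stats::ppoints(n))
    pixels[mask] <- q[rank(v, ties.method = "first")]
  }
  roi_image(pixels, mask, meta = meta)
}

# row-normalized Gaussian smoothing band matrix
.gauss_band <- function(n, sigma) {
  idx <- seq_len(n)
  k <- exp(-0.5 * (outer(idx, idx, "-") / sigma)^2)
  k / rowSums(k)
}

.ellipse_mask <- function(nr, nc, axes, jitter_amp = 0.06, seed_phase = NULL) {
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  y <- matrix(seq_len(nr), nr, nc) - cy
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  phi <- atan2(y, x)
  k <- sample(2:4, 1L)
  ph <- stats::runif(1L, 0, 2 * pi)
  wobble <- 1 + jitter_amp * sin(k * phi + ph)
  (y / (axes[2L] * wobble))^2 + (x / (axes[1L] * wobble))^2 <= 1
}

# binary erosion/dilation with a disc brush (EBImage)
.perturb_mask <- function(mask, radius, dilate) {
  if (radius <= 0L) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- if (dilate) EBImage::dilate(m, brush) else EBImage::erode(m, brush)
  matrix(as.logical(out > 0), nrow(mask), ncol(mask))
}

#' Generate the full synthetic cohort
#'
#' For every patient, slice and sequence, one tumor and one edema ROI per
#' reader.  Masks are drawn once per patient/slice/tissue (reader A), reader
#' B's mask is a small erosion or dilation of reader A's on the same pixel
#' field, and the same masks are replicated across all five sequences.
#' The ground-truth ledger records which feature family was planted as
#' discriminative in each arm and the per-sequence shift sign.
#'
#' @param spec a `cohort_spec`.
#' @return list of class `cohort`: `rois` (list of `roi_image`), `ledger`
#'   (planted families, shift signs, Dice overlaps of the reader masks),
#'   `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  rois <- list()
  dice <- numeric(0)
  nrr <- spec$raster[1L]; ncc <- spec$raster[2L]
  for (disease in names(spec$n_patients)) {
    for (pt in seq_len(spec$n_patients[[disease]])) {
      pid <- sprintf("%s%02d", substr(disease, 1L, 1L), pt)
      jit <- stats::rnorm(1L, 0, spec$patient_jitter_sd) * spec$noise_sd
      for (sl in seq_len(spec$slices_per_patient)) {
        for (tissue in .TISSUES) {
          axes <- sort(stats::runif(2L, spec$axes_range[1L],
                                    spec$axes_range[2L]), decreasing = TRUE)
          mask_a <- .ellipse_mask(nrr, ncc, axes)
          mask_b <- .reader_b_mask(mask_a, spec)
          dice <- c(dice, .dice(mask_a, mask_b))
          if (disease == "GBM") {
            corr <- spec$texture_corr_len[[tissue]]
          } else {
            corr <- spec$menin_corr_len
          }
          for (sq in spec$sequences) {
            mu <- spec$base_mean[[sq]] + jit
            if (disease == "meningioma" && tissue == "tumor") {
              mu <- mu + spec$shift_sign[[sq]] *
                spec$first_order_shift * spec$noise_sd
            }
            # GBM arm: marginal histograms matched exactly so only the
            # spatial (second-order) structure differs between tissues
            roi_a <- generate_textured_roi(mu, spec$noise_sd, corr,
                                           shape = spec$raster,
                                           mask = mask_a,
                                           marginal = if (disease == "GBM")
                                             "exact" else "moment",
                                           meta = list(patient_id = pid,
                                                       sequence = sq,
                                                       tissue = tissue,
                                                       reader = "A",
                                                       disease = disease))
            # reader B contours the same image: same pixel field, own mask
            roi_b <- roi_image(roi_a$pixels, mask_b,
                               meta = utils::modifyList(roi_a$meta,
                                                        list(reader = "B")))
            roi_a$meta$slice <- sl; roi_b$meta$slice <- sl
            rois[[length(rois) + 1L]] <- roi_a
            rois[[length(rois) + 1L]] <- roi_b
          }
        }
      }
    }
  }
  ledger <- list(
    planted_family = c(GBM = "GLCM", meningioma = "HIST"),
    shift_sign = spec$shift_sign,
    first_order_shift = spec$first_order_shift,
    texture_corr_len = spec$texture_corr_len,
    reader_dice = c(min = min(dice), mean = base::mean(dice))
  )
  structure(list(rois = rois, ledger = ledger, spec = spec),
            class = "cohort")
}

.reader_b_mask <- function(mask_a, spec, min_pixels = 16L, max_tries = 8L) {
  lo <- spec$reader_perturbation[1L]
  hi <- spec$reader_perturbation[length(spec$reader_perturbation)]
  for (i in seq_len(max_tries)) {
    radius <- sample(seq.int(lo, hi), 1L)
    dilate <- stats::runif(1L) < 0.5
    m <- .perturb_mask(mask_a, radius, dilate)
    if (sum(m) >= min_pixels && .dice(mask_a, m) >= 0.8) return(m)
  }
  stop("could not derive a valid reader-B mask after ", max_tries, " tries")
}

.dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d ROIs, %d+%d patients, Dice(A,B) min %.3f>\n",
              length(x$rois), x$spec$n_patients[[1L]],
              x$spec$n_patients[[2L]], x$ledger$reader_dice[["min"]]))
  invisible(x)
}
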