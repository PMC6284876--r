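# ROI containers and image/mask I/O.
#
# An ROI is a float intensity raster plus a same-shape boolean mask plus
# metadata (patient, sequence, tissue, reader, disease).  Real data arrives
# as NIfTI slices; tests and the synthetic cohort use a plain CSV raster
# dialect (one CSV per raster, sidecar JSON for metadata) so that nothing
# binary is needed anywhere in the workflow.

#' Construct an ROI image
#'
#' @param pixels numeric matrix of intensities (arbitrary MR units).
#' @param mask logical (or 0/1) matrix of the same shape; `TRUE`/nonzero =
#'   inside the ROI.
#' @param meta named list with any of `patient_id`, `sequence` (one of
#'   FLAIR, ADC, T1W, T1W_C, T2W), `tissue` (tumor/edema), `reader` (A/B),
#'   `disease` (GBM/meningioma).  Unknown entries are kept as-is.
#' @param min_roi_pixels smallest admissible mask size; texture features are
#'   not meaningful on tiny regions, so the default floor is 16 pixels.
#' @return object of class `roi_image` with elements `pixels`, `mask`,
#'   `meta`, and (after normalization) a `normalization` tag.
#' @export
roi_image <- function(pixels, mask, meta = list(), min_roi_pixels = 16L) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  mask <- as.matrix(mask)
  if (!identical(dim(pixels), dim(mask))) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match pixel shape ", paste(dim(pixels), collapse = "x"))
  }
  mask <- mask != 0
  mask[is.na(mask)] <- FALSE
  n_in <- sum(mask)
  if (n_in == 0L) stop("empty mask: ROI contains no pixels")
  if (n_in < min_roi_pixels) {
    stop("mask has ", n_in, " pixels; at least ", min_roi_pixels,
         " are required for feature extraction")
  }
  if (any(!is.finite(pixels[mask]))) stop("non-finite intensities inside mask")
  stopifnot(is.list(meta))
  .check_meta(meta)
  structure(list(pixels = pixels, mask = mask, meta = meta,
                 normalization = "none"),
            class = "roi_image")
}

.check_meta <- function(meta) {
  chk <- function(field, allowed) {
    v <- meta[[field]]
    if (!is.null(v) && !v %in% allowed) {
      stop("meta$", field, " must be one of: ", paste(allowed, collapse = ", "))
    }
  }
  chk("sequence", .SEQUENCES)
  chk("tissue", .TISSUES)
  chk("reader", .READERS)
  chk("disease", .DISEASES)
  invisible(TRUE)
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image %dx%d, %d masked px, normalization=%s>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$mask), x$normalization))
  m <- x$meta
  if (length(m)) {
    cat(" ", paste(names(m), unlist(m), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Masked intensities of an ROI
#' @param roi an `roi_image`.
#' @return numeric vector of in-mask pixel values.
#' @export
roi_values <- function(roi) roi$pixels[roi$mask]

# ---------------------------------------------------------------------------
# readers / writers

#' Read an ROI from disk
#'
#' Supports two storage formats behind one contract: the plain CSV raster
#' dialect (headerless numeric CSV, one row per image row) and NIfTI-1
#' (a 2D slice extracted by index via the RNifti reader).  The mask is read
#' from the same format as the image; any nonzero mask value means inside.
#'
#' @param image_path path to intensity raster (`.csv` or `.nii`/`.nii.gz`).
#' @param mask_path path to mask raster, same grid.
#' @param meta metadata list, see [roi_image()].
#' @param slice slice index for 3D NIfTI volumes (third dimension).
#' @param min_roi_pixels see [roi_image()].
#' @return an `roi_image`.
#' @export
read_roi <- function(image_path, mask_path, meta = list(), slice = 1L,
                     min_roi_pixels = 16L) {
  pixels <- .read_raster(image_path, slice)
  mask <- .read_raster(mask_path, slice)
  roi_image(pixels, mask, meta = meta, min_roi_pixels = min_roi_pixels)
}

.read_raster <- function(path, slice = 1L) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    m
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) == 2L) a else a[, , slice]
  } else {
    stop("unsupported raster format: ", path,
         " (expected .csv or .nii/.nii.gz)")
  }
}

#' Write an ROI in the CSV fixture dialect
#'
#' Writes `<stem>.csv` (intensities), `<stem>_mask.csv` (0/1 mask) and
#' `<stem>.json` (metadata).  [read_roi_csv()] round-trips these bit-exactly:
#' intensities are serialized with full precision.
#'
#' @param roi an `roi_image`.
#' @param stem path stem (no extension).
#' @return invisibly, the three paths written.
#' @export
write_roi <- function(roi, stem) {
  img_path <- paste0(stem, ".csv")
  mask_path <- paste0(stem, "_mask.csv")
  meta_path <- paste0(stem, ".json")
  .write_raster(roi$pixels, img_path)
  .write_raster(roi$mask + 0L, mask_path)
  jsonlite::write_json(roi$meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, mask = mask_path, meta = meta_path))
}

.write_raster <- function(m, path) {
  lines <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = ","))
  writeLines(lines, path)
}

#' Read an ROI written by [write_roi()]
#' @param stem path stem used at write time.
#' @param min_roi_pixels see [roi_image()].
#' @return an `roi_image`.
#' @export
read_roi_csv <- function(stem, min_roi_pixels = 16L) {
  meta_path <- paste0(stem, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  read_roi(paste0(stem, ".csv"), paste0(stem, "_mask.csv"),
           meta = as.list(meta), min_roi_pixels = min_roi_pixels)
}

# ---------------------------------------------------------------------------
# mask transfer and ADC computation

#' Replicate a segmented mask onto a co-registered sequence
#'
#' Mirrors the study design where each ROI is contoured once and the same
#' contour is replicated across the other co-registered MR sequences.  On the
#' same grid the mask is copied bit-for-bit; on a different (but aligned)
#' grid it is resampled by nearest neighbor, and the transfer is rejected if
#' the in-mask area fraction changes by more than 20% (a proxy for a failed
#' registration).
#'
#' @param source an `roi_image` carrying the mask to transfer.
#' @param target_pixels intensity raster of the target sequence.
#' @param meta metadata for the resulting ROI (defaults to the source's).
#' @param tol_fraction maximum allowed relative change in mask area fraction.
#' @return an `roi_image` on the target grid.
#' @export
transfer_mask <- function(source, target_pixels, meta = source$meta,
                          tol_fraction = 0.2) {
  target_pixels <- as.matrix(target_pixels)
  sdim <- dim(source$mask)
  tdim <- dim(target_pixels)
  if (identical(sdim, tdim)) {
    return(roi_image(target_pixels, source$mask, meta = meta))
  }
  # nearest-neighbor index mapping from target grid back onto source grid
  ri <- pmin(sdim[1L], pmax(1L, round((seq_len(tdim[1L]) - 0.5) *
                                        sdim[1L] / tdim[1L] + 0.5)))
  ci <- pmin(sdim[2L], pmax(1L, round((seq_len(tdim[2L]) - 0.5) *
                                        sdim[2L] / tdim[2L] + 0.5)))
  new_mask <- source$mask[ri, ci, drop = FALSE]
  src_frac <- mean(source$mask)
  new_frac <- mean(new_mask)
  if (src_frac == 0 || abs(new_frac - src_frac) / src_frac > tol_fraction) {
    stop("mask transfer failed: in-mask fraction changed from ",
         signif(src_frac, 4), " to ", signif(new_frac, 4),
         " (limit ", tol_fraction * 100, "%)")
  }
  roi_image(target_pixels, new_mask, meta = meta)
}

#' Voxelwise apparent diffusion coefficient map
#'
#' ADC computed from two diffusion-weighted acquisitions, pixel by pixel:
#' `ADC = ln(S0 / Sb) / b1` in mm^2/s, where `S0` is the signal at
#' b = 0 s/mm^2 and `Sb` at `b1` (default 1000 s/mm^2).  Signals are floored
#' at `epsilon` (default 1e-6 of the median `S0`) so zero-signal pixels give
#' a large finite value instead of an infinity.
#'
#' @param s0 signal raster at b = 0.
#' @param sb signal raster at b = `b1`; same shape as `s0`.
#' @param b1 b-value of `sb` in s/mm^2; must be positive.
#' @param epsilon signal floor; default `1e-6 * median(s0)` (or 1e-6 when the
#'   median is zero).
#' @return numeric matrix of ADC values (mm^2/s).
#' @export
compute_adc <- function(s0, sb, b1 = 1000, epsilon = NULL) {
  s0 <- as.matrix(s0); sb <- as.matrix(sb)
  if (!identical(dim(s0), dim(sb))) stop("s0 and sb must share a grid")
  if (b1 <= 0) stop("b1 must be positive")
  if (any(s0 < 0) || any(sb < 0)) stop("negative diffusion signals")
  if (is.null(epsilon)) {
    m <- stats::median(s0)
    epsilon <- if (m > 0) 1e-6 * m else 1e-6
  }
  if (epsilon <= 0) stop("epsilon must be positive")
  log(pmax(s0, epsilon) / pmax(sb, epsilon)) / b1
}
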