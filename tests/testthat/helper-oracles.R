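# Independent brute-force oracles used to validate the vectorized
# implementations.  Each one is a direct transcription of the defining
# construction (explicit loops, no shared code with the package internals).

# ordered-pair co-occurrence counts by exhaustive pixel enumeration
oracle_glcm_counts <- function(levels, mask, d, theta) {
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  ng <- max(levels)
  counts <- matrix(0L, ng, ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          mask[r, c] && mask[r2, c2]) {
        i <- levels[r, c]; j <- levels[r2, c2]
        counts[i, j] <- counts[i, j] + 1L
      }
    }
  }
  counts
}

# maximal-run enumeration by explicit line tracing
oracle_glrlm <- function(levels, mask, theta) {
  nr <- nrow(levels); nc <- ncol(levels)
  step <- switch(as.character(theta),
                 "0" = c(0, 1), "90" = c(1, 0),
                 "45" = c(-1, 1), "135" = c(1, 1))
  starts <- switch(as.character(theta),
    "0"   = lapply(seq_len(nr), function(r) c(r, 1)),
    "90"  = lapply(seq_len(nc), function(c) c(1, c)),
    # anti-diagonals start on the left column or bottom row
    "45"  = c(lapply(seq_len(nr), function(r) c(r, 1)),
              lapply(seq.int(2, nc), function(c) c(nr, c))),
    # main diagonals start on the top row or left column
    "135" = c(lapply(seq_len(nc), function(c) c(1, c)),
              lapply(seq.int(2, nr), function(r) c(r, 1))))
  runs <- list()
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur_val <- 0L; cur_len <- 0L
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- if (mask[r, c]) levels[r, c] else 0L
      if (v == cur_val) {
        cur_len <- cur_len + 1L
      } else {
        if (cur_val > 0L) runs[[length(runs) + 1L]] <- c(cur_val, cur_len)
        cur_val <- v; cur_len <- 1L
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (cur_val > 0L) runs[[length(runs) + 1L]] <- c(cur_val, cur_len)
  }
  if (!length(runs)) return(matrix(0L, 1, 1))
  m <- do.call(rbind, runs)
  ng <- max(levels)
  out <- matrix(0L, ng, max(m[, 2]))
  for (k in seq_len(nrow(m))) {
    out[m[k, 1], m[k, 2]] <- out[m[k, 1], m[k, 2]] + 1L
  }
  out
}

# Mann-Whitney AUC by exhaustive pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# type-7 percentile by sorting and interpolating between closest ranks
oracle_percentile <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# random quantized image with a random (non-empty) mask
random_masked_image <- function(nr, nc, ng, p_mask = 0.7) {
  lev <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(runif(nr * nc) < p_mask, nr, nc)
  if (!any(mask)) mask[sample.int(nr * nc, 1)] <- TRUE
  lev[!mask] <- 0L
  list(levels = lev, mask = mask, ng = ng)
}

# wrap a level raster as the quantized_roi structure the package consumes
as_qroi <- function(im) {
  structure(list(levels = im$levels, n_levels = im$ng, mask = im$mask,
                 rule = list(mode = "raw_range", lower_bound = 0,
                             upper_bound = 1, degenerate = FALSE)),
            class = "quantized_roi")
}

# small fully-masked ROI from a plain matrix
roi_from_matrix <- function(m, min_roi_pixels = 1L) {
  roi_image(m, matrix(TRUE, nrow(m), ncol(m)),
            min_roi_pixels = min_roi_pixels)
}
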