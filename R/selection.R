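# Feature selection: per-reader L1-penalized logistic regression with
# cross-validated penalty, and cross-reader consensus by intersection.
#
# The study's procedure: each reader's feature table is analyzed
# independently with a binomial-family, logit-link LASSO; the penalty is
# chosen by cross-validation as the value minimizing the prediction error
# (deviance); and only the features selected for BOTH readers are retained.
# An empty intersection is a real outcome ("no agreement"), reported, not
# an error.

#' LASSO logistic selection of tumor-vs-edema discriminators
#'
#' Fits an L1-penalized logistic regression (glmnet, binomial family, logit
#' link) of tissue label on z-standardized features over the full lambda
#' path, picks the lambda minimizing 10-fold cross-validated deviance with a
#' seeded, class-stratified fold assignment, and returns the features with
#' nonzero coefficients at that lambda.  Coefficients are mapped back to the
#' raw feature scale.  Zero-variance and undefined-flagged columns are
#' dropped before fitting (they carry no usable signal).
#'
#' @param x numeric matrix or data.frame of features (rows = ROIs); columns
#'   containing `NA` (undefined-flagged features) are dropped.
#' @param y binary labels: 1/"tumor" = tumor, 0/"edema" = edema.
#' @param folds number of cross-validation folds (>= 3; default 10).
#' @param seed seed for the fold assignment; fixing it makes the selected
#'   set bit-reproducible.  Default 20181008.
#' @return list with `selected` (character), `coefficients` (named numeric,
#'   raw scale, nonzero only), `intercept`, `lambda`, `n_used_features`.
#' @export
fit_lasso_logistic <- function(x, y, folds = 10L, seed = 20181008L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- .as_label(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (folds < 3L) stop("folds must be >= 3")

  keep <- apply(x, 2L, function(col) !anyNA(col) && stats::sd(col) > 0)
  xk <- x[, keep, drop = FALSE]
  if (ncol(xk) == 0L) stop("no usable feature columns")
  mu <- colMeans(xk)
  sdev <- apply(xk, 2L, stats::sd)
  xs <- scale(xk, center = mu, scale = sdev)

  # class-stratified fold labels under a local seed
  foldid <- integer(length(y))
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  # small per-fold class counts are inherent to per-scenario sample sizes;
  # glmnet warns about them on every fit, so that warning is muffled here
  cvfit <- withCallingHandlers(
    glmnet::cv.glmnet(xs, y, family = "binomial",
                      type.measure = "deviance", foldid = foldid,
                      standardize = FALSE),
    warning = function(w) {
      # also muffle the small-lambda non-convergence notice: separable
      # scenarios are legal here and glmnet returns the valid larger-lambda
      # path, which is all that lambda.min selection uses
      if (grepl(paste0("fewer than 8\\s+observations|",
                       "grouped=FALSE enforced|",
                       "Convergence for .* lambda value"),
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  lambda <- cvfit$lambda.min
  beta <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  b <- beta[-1L, 1L]
  nz <- which(b != 0)
  sel <- colnames(xs)[nz]
  coefs_raw <- b[nz] / sdev[nz]
  a0_raw <- beta[1L, 1L] - sum(b[nz] * mu[nz] / sdev[nz])
  list(selected = sel,
       coefficients = stats::setNames(as.numeric(coefs_raw), sel),
       intercept = as.numeric(a0_raw),
       lambda = lambda,
       n_used_features = ncol(xk))
}

.as_label <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), .TISSUES)
    if (length(bad)) stop("unknown tissue labels: ", paste(bad, collapse = ", "))
    as.integer(y == "tumor")
  } else {
    as.integer(y != 0)
  }
}

#' Cross-reader consensus of two selection runs
#'
#' Intersects two per-reader selected sets computed on the same feature
#' namespace.  Status is `"ok"` for a nonempty intersection,
#' `"none_selected"` when both per-reader sets are empty, and
#' `"no_agreement"` when at least one reader selected features but the
#' intersection is empty (rendered `NA` in reports).
#'
#' @param a,b per-reader results from [fit_lasso_logistic()] (or any lists
#'   with `selected` and `n_used_features`).
#' @return list of class `selection_result`: `per_reader` (named list of
#'   the two inputs), `consensus` (character), `lambda` (named numeric),
#'   `status`.
#' @export
consensus_selection <- function(a, b) {
  if (!is.null(a$n_used_features) && !is.null(b$n_used_features) &&
      a$n_used_features != b$n_used_features) {
    # readers can drop different degenerate columns, but the namespace used
    # must coincide for the intersection to mean anything
    stop("per-reader runs used different feature namespaces")
  }
  consensus <- intersect(a$selected, b$selected)
  status <- if (length(consensus)) {
    "ok"
  } else if (length(a$selected) == 0L && length(b$selected) == 0L) {
    "none_selected"
  } else {
    "no_agreement"
  }
  structure(list(per_reader = list(A = a, B = b),
                 consensus = consensus,
                 lambda = c(A = a$lambda %||% NA_real_,
                            B = b$lambda %||% NA_real_),
                 status = status),
            class = "selection_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result status=%s consensus={%s}>\n", x$status,
              paste(x$consensus, collapse = ", ")))
  invisible(x)
}

#' Per-scenario selection over a feature table
#'
#' Splits a long feature table by scenario (disease x normalization x
#' sequence), runs the per-reader LASSO within each scenario and intersects
#' across readers.  Scenarios with fewer than 2 ROIs per class per reader
#' are skipped with a logged reason.
#'
#' @param table feature table from [run_extract()]: meta columns
#'   (`patient_id`, `slice`, `sequence`, `tissue`, `reader`, `disease`,
#'   `normalization`) plus feature columns.
#' @param folds,seed passed to [fit_lasso_logistic()].
#' @return named list (key `"disease|normalization|sequence"`) of
#'   `selection_result` objects; skipped scenarios carry status
#'   `"skipped"` and a `reason`.
#' @export
select_per_scenario <- function(table, folds = 10L, seed = 20181008L) {
  meta_cols <- .META_COLS
  feats <- setdiff(colnames(table), meta_cols)
  key <- interaction(table$disease, table$normalization, table$sequence,
                     sep = "|", drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    sub <- table[key == k, , drop = FALSE]
    per_reader <- list()
    skip <- NULL
    for (rd in .READERS) {
      srd <- sub[sub$reader == rd, , drop = FALSE]
      tab <- table(srd$tissue)
      if (length(tab) < 2L || any(tab < 2L)) {
        skip <- paste0("reader ", rd, ": fewer than 2 ROIs per class")
        break
      }
      per_reader[[rd]] <- fit_lasso_logistic(srd[, feats, drop = FALSE],
                                             srd$tissue, folds = folds,
                                             seed = seed)
    }
    out[[k]] <- if (is.null(skip)) {
      consensus_selection(per_reader$A, per_reader$B)
    } else {
      structure(list(per_reader = NULL, consensus = character(),
                     lambda = c(A = NA_real_, B = NA_real_),
                     status = "skipped", reason = skip),
                class = "selection_result")
    }
  }
  out
}

.META_COLS <- c("patient_id", "slice", "sequence", "tissue", "reader",
                "disease", "normalization")
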