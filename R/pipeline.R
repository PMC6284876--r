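# Pipeline orchestration: extract -> select -> evaluate over the scenario
# grid (disease x normalization x sequence), plus report rendering.

#' Extract a feature table from a set of ROIs
#'
#' Runs [extract_features()] on every ROI under each requested normalization
#' mode and assembles one long table: the meta columns (`patient_id`,
#' `slice`, `sequence`, `tissue`, `reader`, `disease`, `normalization`)
#' followed by one column per feature.  Undefined-flagged features are
#' stored as `NA` so no placeholder zero can leak into a model silently;
#' selection drops such columns per scenario.  Per-ROI failures are caught,
#' logged to the returned `skipped` attribute and dropped, never silent.
#'
#' @param rois list of `roi_image` objects (e.g. `cohort$rois`).
#' @param normalization subset of `c("none", "p1_99")` (default both).
#' @param n_levels,distances,angles,n_bins see [extract_features()].
#' @return data.frame feature table; `attr(, "skipped")` lists failures.
#' @export
run_extract <- function(rois, normalization = c("none", "p1_99"),
                        n_levels = 64L, distances = 1:5, angles = .ANGLES,
                        n_bins = 256L) {
  normalization <- match.arg(normalization, several.ok = TRUE)
  rows <- list(); skipped <- character()
  for (nm in normalization) {
    for (i in seq_along(rois)) {
      roi <- rois[[i]]
      f <- tryCatch(
        extract_features(roi, normalization = nm, n_levels = n_levels,
                         distances = distances, angles = angles,
                         n_bins = n_bins),
        error = function(e) e)
      if (inherits(f, "error")) {
        skipped <- c(skipped, sprintf("roi %d (%s): %s", i, nm,
                                      conditionMessage(f)))
        next
      }
      vals <- stats::setNames(as.numeric(f), names(f))
      vals[feature_undefined(f)] <- NA_real_
      m <- roi$meta
      rows[[length(rows) + 1L]] <- c(
        list(patient_id = m$patient_id %||% NA_character_,
             slice = m$slice %||% NA_integer_,
             sequence = m$sequence %||% NA_character_,
             tissue = m$tissue %||% NA_character_,
             reader = m$reader %||% NA_character_,
             disease = m$disease %||% NA_character_,
             normalization = nm),
        as.list(vals))
    }
  }
  if (!length(rows)) stop("no ROI produced features")
  nms <- names(rows[[1L]])
  if (!all(vapply(rows, function(r) identical(names(r), nms), logical(1)))) {
    stop("inconsistent feature namespaces across ROIs")
  }
  tab <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  })), stringsAsFactors = FALSE)
  attr(tab, "skipped") <- skipped
  tab
}

#' Write / read a feature table as CSV
#'
#' Full-precision serialization so that identical runs produce byte-identical
#' files (the determinism contract of the pipeline).
#'
#' @param table feature table from [run_extract()].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(out[num], function(col) {
    ifelse(is.na(col), "",
           format(col, digits = 17, trim = TRUE, scientific = TRUE))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  feats <- setdiff(colnames(tab), .META_COLS)
  tab[feats] <- lapply(tab[feats], as.numeric)
  tab
}

#' Run the full pipeline on a cohort
#'
#' Extraction over both normalization modes, per-reader LASSO selection and
#' cross-reader consensus in every scenario, ROC/threshold evaluation, and
#' the inter-rater kappa on the tissue classifications (the readers label
#' the same regions, so on this design kappa is the agreement the study
#' reported).  Scenario grid = diseases x normalizations x sequences; every
#' scenario appears exactly once in the report.
#'
#' @param cohort a `cohort` from [generate_cohort()] (or a list with
#'   `rois`).
#' @param normalization normalization modes to run (default both).
#' @param n_levels,distances,angles,n_bins extraction settings.
#' @param folds,seed selection settings, see [fit_lasso_logistic()].
#' @return list of class `radtex_report`: `features` (the long table),
#'   `selections`, `evaluation` (`summary` + `details`), `kappa`,
#'   `skipped`.
#' @export
run_full <- function(cohort, normalization = c("none", "p1_99"),
                     n_levels = 64L, distances = 1:5, angles = .ANGLES,
                     n_bins = 256L, folds = 10L, seed = 20181008L) {
  rois <- if (inherits(cohort, "cohort")) cohort$rois else cohort
  table <- run_extract(rois, normalization = normalization,
                       n_levels = n_levels, distances = distances,
                       angles = angles, n_bins = n_bins)
  selections <- select_per_scenario(table, folds = folds, seed = seed)
  evaluation <- evaluate_scenarios(selections, table)
  kappa <- .reader_kappa(table)
  structure(list(features = table, selections = selections,
                 evaluation = evaluation, kappa = kappa,
                 skipped = attr(table, "skipped")),
            class = "radtex_report")
}

# agreement of the two readers' tissue classifications, paired by
# patient/slice/sequence/tissue identity of the contoured region
.reader_kappa <- function(table) {
  sub <- table[table$normalization == table$normalization[1L], , drop = FALSE]
  key <- with(sub, paste(patient_id, slice, sequence, tissue))
  a <- sub[sub$reader == "A", , drop = FALSE]
  b <- sub[sub$reader == "B", , drop = FALSE]
  ka <- with(a, paste(patient_id, slice, sequence, tissue))
  kb <- with(b, paste(patient_id, slice, sequence, tissue))
  common <- intersect(ka, kb)
  cohens_kappa(a$tissue[match(common, ka)], b$tissue[match(common, kb)])
}

#' @export
print.radtex_report <- function(x, ...) {
  s <- x$evaluation$summary
  cat(sprintf("<radtex_report: %d scenarios (%d ok, %d NA/none), kappa=%.3f>\n",
              nrow(s), sum(s$status == "ok"), sum(s$status != "ok"),
              x$kappa))
  invisible(x)
}

#' Render the selection/evaluation report as display text
#'
#' One row per scenario with the selected parameters, the most useful
#' parameter, its AUC and 95% CI, and perfect-classification rules where
#' found; `NA` marks no-agreement scenarios and `None Selected` marks
#' scenarios where neither reader's LASSO kept anything.
#'
#' @param report a `radtex_report`.
#' @return data.frame with display-formatted columns.
#' @export
render_report <- function(report) {
  s <- report$evaluation$summary
  data.frame(
    Disease = s$disease,
    Normalization = ifelse(s$normalization == "none",
                           "Non-normalized", "Normalized"),
    Sequence = s$sequence,
    Parameters = s$parameters,
    MostUseful = ifelse(is.na(s$most_useful), "NA", s$most_useful),
    AUC = ifelse(is.na(s$auc), "NA",
                 ifelse(!is.na(s$perfect_rules), "PC",
                        sprintf("%.2f (%.2f-%.2f)", s$auc, s$ci_low,
                                s$ci_high))),
    PerfectRule = ifelse(is.na(s$perfect_rules), "", s$perfect_rules),
    stringsAsFactors = FALSE)
}
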