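# Evaluation: ROC/AUC with DeLong confidence intervals, perfect-threshold
# discovery, Cohen's kappa, and the per-scenario report.

#' ROC analysis of a single score against tissue labels
#'
#' AUC as the Mann-Whitney statistic, `P(score_tumor > score_edema) +
#' 0.5 P(equal)` over all positive-negative pairs, with a 95% DeLong
#' confidence interval (both via pROC).  Orientation is chosen so that the
#' reported AUC is >= 0.5, with the direction recorded: `greater_is_tumor`
#' when high scores indicate tumor, `less_is_tumor` otherwise.
#'
#' @param scores numeric scores, one per ROI.
#' @param labels binary labels (1/"tumor" = tumor).
#' @return object of class `roc_result`: `auc`, `ci_low`, `ci_high`
#'   (clipped to `[0, 1]`), `n_pos`, `n_neg`, `direction`, `degenerate`
#'   (TRUE when all scores are tied, AUC fixed at 0.5 with no usable CI).
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_label(labels)
  scores <- as.numeric(scores)
  if (length(scores) != length(y)) stop("scores and labels sizes differ")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  if (length(unique(scores)) < 2L) {
    return(structure(list(auc = 0.5, ci_low = NA_real_, ci_high = NA_real_,
                          n_pos = n_pos, n_neg = n_neg,
                          direction = "greater_is_tumor", degenerate = TRUE),
                     class = "roc_result"))
  }
  # pROC direction "<" means controls (edema) score below cases (tumor)
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  if (auc >= 0.5) {
    direction <- "greater_is_tumor"
  } else {
    r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                   direction = ">", quiet = TRUE)
    auc <- as.numeric(pROC::auc(r))
    direction <- "less_is_tumor"
  }
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  structure(list(auc = auc,
                 ci_low = max(0, min(1, ci[1L])),
                 ci_high = max(0, min(1, ci[3L])),
                 n_pos = n_pos, n_neg = n_neg, direction = direction,
                 degenerate = FALSE),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result AUC=%.3f (%.3f-%.3f), %d tumor vs %d edema, %s>\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' Single-feature threshold rule, perfect where possible
#'
#' If the tumor and edema value ranges are disjoint, returns the perfect
#' rule: direction `<` (tumor below the cut) or `>` with the cut at the
#' midpoint between the two boundary observations.  Otherwise returns the
#' accuracy-maximizing rule over all midpoints between adjacent distinct
#' values, ties broken toward the smaller cut, with `perfect = FALSE`.
#'
#' @param values numeric feature values.
#' @param labels binary labels (1/"tumor" = tumor).
#' @param feature optional feature name carried into the rule.
#' @return list of class `threshold_rule` (`feature`, `direction`, `cut`,
#'   `perfect`, `accuracy`), or `NULL` for a constant feature.
#' @export
find_perfect_threshold <- function(values, labels, feature = NA_character_) {
  y <- .as_label(labels)
  values <- as.numeric(values)
  if (length(values) != length(y)) stop("values and labels sizes differ")
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop("both classes must be present")
  }
  tv <- values[y == 1L]; ev <- values[y == 0L]
  if (length(unique(values)) < 2L) return(NULL)

  rule <- function(direction, cut, perfect, accuracy) {
    structure(list(feature = feature, direction = direction, cut = cut,
                   perfect = perfect, accuracy = accuracy),
              class = "threshold_rule")
  }
  if (max(tv) < min(ev)) {
    return(rule("<", (max(tv) + min(ev)) / 2, TRUE, 1))
  }
  if (min(tv) > max(ev)) {
    return(rule(">", (min(tv) + max(ev)) / 2, TRUE, 1))
  }
  u <- sort(unique(values))
  cuts <- (u[-1L] + u[-length(u)]) / 2
  best <- NULL
  for (cut in cuts) {
    for (direction in c("<", ">")) {
      pred <- if (direction == "<") as.integer(values < cut)
              else as.integer(values > cut)
      acc <- mean(pred == y)
      if (is.null(best) || acc > best$accuracy) {
        best <- rule(direction, cut, FALSE, acc)
      }
    }
  }
  best
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule %s %s %.6g%s (acc %.3f)>\n",
              if (is.na(x$feature)) "value" else x$feature, x$direction,
              x$cut, if (x$perfect) " [perfect]" else "", x$accuracy))
  invisible(x)
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` over the
#' cross-table of two equal-length categorical label sequences.  Degenerate
#' rule: when both raters are constant (`p_e = 1`), kappa is 1 if they agree
#' on the level (`p_o = 1`) and 0 otherwise.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return kappa (numeric scalar).
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label lengths differ")
  if (length(labels_a) == 0L) stop("empty label sequences")
  lv <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lv)
  b <- factor(as.character(labels_b), levels = lv)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# ---------------------------------------------------------------------------
# scenario-level evaluation

#' Evaluate selected features scenario by scenario
#'
#' For every scenario with a nonempty consensus: a univariate ROC for each
#' consensus feature (rows pooled over the two readers), the "most useful
#' parameter" (highest univariate AUC; exact ties are all reported), an
#' unpenalized logistic refit on the full consensus set whose fitted
#' probabilities give the multivariable model AUC, and a perfect threshold
#' rule per feature where one exists.  Scenarios with no agreement or
#' nothing selected are rendered as `NA` rows, mirroring the tabular
#' convention of the study design.
#'
#' @param selections named list from [select_per_scenario()].
#' @param table the feature table the selections were computed on.
#' @return list with `summary` (data.frame, one row per scenario: disease,
#'   normalization, sequence, status, parameters, most useful parameter,
#'   AUC + CI of the most useful parameter, model AUC, perfect-rule text)
#'   and `details` (per-scenario list of `roc_result`s and
#'   `threshold_rule`s).
#' @export
evaluate_scenarios <- function(selections, table) {
  feats_all <- setdiff(colnames(table), .META_COLS)
  key <- interaction(table$disease, table$normalization, table$sequence,
                     sep = "|", drop = TRUE)
  rows <- list(); details <- list()
  for (k in names(selections)) {
    sel <- selections[[k]]
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    base <- data.frame(disease = parts[1L], normalization = parts[2L],
                       sequence = parts[3L], status = sel$status,
                       parameters = NA_character_,
                       most_useful = NA_character_,
                       auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       model_auc = NA_real_, perfect_rules = NA_character_,
                       stringsAsFactors = FALSE)
    if (sel$status != "ok") {
      base$parameters <- if (sel$status == "none_selected") "None Selected"
                         else "NA"
      rows[[k]] <- base
      next
    }
    sub <- table[key == k, , drop = FALSE]
    y <- sub$tissue
    fr <- list(); rules <- list()
    for (f in sel$consensus) {
      fr[[f]] <- roc_auc(sub[[f]], y)
      rl <- find_perfect_threshold(sub[[f]], y, feature = f)
      if (!is.null(rl)) rules[[f]] <- rl
    }
    aucs <- vapply(fr, function(r) r$auc, numeric(1))
    best <- names(aucs)[aucs == max(aucs)]
    model_auc <- if (length(sel$consensus) == 1L) {
      max(aucs)
    } else {
      X <- as.data.frame(sub[, sel$consensus, drop = FALSE])
      X$.y <- .as_label(y)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = X,
                                         family = stats::binomial()))
      roc_auc(stats::predict(fit, type = "response"), y)$auc
    }
    pr <- Filter(function(r) isTRUE(r$perfect), rules)
    base$parameters <- paste(sel$consensus, collapse = "; ")
    base$most_useful <- paste(best, collapse = "; ")
    base$auc <- max(aucs)
    base$ci_low <- fr[[best[1L]]]$ci_low
    base$ci_high <- fr[[best[1L]]]$ci_high
    base$model_auc <- model_auc
    base$perfect_rules <- if (length(pr)) {
      paste(vapply(pr, function(r) sprintf("%s %s %.6g", r$feature,
                                           r$direction, r$cut),
                   character(1)), collapse = "; ")
    } else NA_character_
    rows[[k]] <- base
    details[[k]] <- list(roc = fr, rules = rules)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, details = details)
}
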