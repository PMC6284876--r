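# Feature vectors: named numeric values plus an explicit set of
# undefined-flagged names.  A feature whose defining formula has a zero
# denominator (zero variance, empty matrix, ...) is returned as 0 with its
# name recorded in the "undefined" attribute -- never as a silent NaN.

fv <- function(values, undefined = character()) {
  stopifnot(!is.null(names(values)), !anyDuplicated(names(values)))
  values[names(values) %in% undefined] <- 0
  structure(as.numeric(values), names = names(values),
            undefined = undefined, class = "feature_vector")
}

fv_concat <- function(...) {
  parts <- list(...)
  vals <- unlist(lapply(parts, function(p) {
    v <- as.numeric(p); names(v) <- names(p); v
  }))
  und <- unlist(lapply(parts, feature_undefined))
  if (anyDuplicated(names(vals))) stop("duplicate feature names on concat")
  fv(vals, undefined = und)
}

#' Names of undefined-flagged features
#' @param x a feature vector returned by the extraction functions.
#' @return character vector of feature names whose value is a 0 placeholder
#'   because the defining formula was undefined on this input.
#' @export
feature_undefined <- function(x) {
  u <- attr(x, "undefined")
  if (is.null(u)) character() else u
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector: %d features, %d undefined>\n",
              length(x), length(feature_undefined(x))))
  print(utils::head(stats::setNames(as.numeric(x), names(x)), 10L))
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

# suffix helpers for the per-(d, theta) blocks
.angle_tag <- function(theta) sprintf("a%03d", as.integer(theta))
.dist_tag <- function(d) sprintf("d%d", as.integer(d))
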