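#!/usr/bin/env Rscript
# Step 3 -- per-reader LASSO selection and cross-reader consensus.
#
# Within each scenario (disease x normalization x sequence), fits an
# L1-penalized logistic regression of tissue (tumor vs edema) on the
# z-standardized features separately for each reader, picks the penalty by
# 10-fold cross-validated deviance, and keeps only the features selected
# for BOTH readers.  An empty intersection is reported as "no agreement";
# two empty selections as "none selected".
#
# Reads results/features.csv (step 2); writes results/selection.json.

library(radtex)

tab <- read_feature_table("results/features.csv")
sels <- select_per_scenario(tab)

status <- vapply(sels, `[[`, character(1), "status")
cat(sprintf("Scenarios: %d ok, %d no agreement, %d none selected.\n",
            sum(status == "ok"), sum(status == "no_agreement"),
            sum(status == "none_selected")))
for (k in names(sels)) {
  s <- sels[[k]]
  cat(sprintf("  %-28s %-14s %s\n", k, s$status,
              paste(s$consensus, collapse = "; ")))
}

out <- lapply(sels, function(s) {
  list(status = s$status,
       consensus = s$consensus,
       lambda = as.list(s$lambda),
       per_reader = if (is.null(s$per_reader)) NULL else
         lapply(s$per_reader, function(p) {
           list(selected = p$selected,
                coefficients = as.list(p$coefficients),
                lambda = p$lambda)
         }))
})
jsonlite::write_json(out, "results/selection.json", auto_unbox = TRUE,
                     digits = NA)
cat("Wrote results/selection.json.\n")
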