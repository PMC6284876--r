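# Shared fixtures built in code.  The default-cohort pipeline run is the
# expensive fixture (a few minutes); it is computed once per test session
# and reused by every test that inspects it.

.fixture_env <- new.env(parent = emptyenv())

default_pipeline_report <- function() {
  if (is.null(.fixture_env$report)) {
    cohort <- generate_cohort(cohort_spec())
    .fixture_env$cohort <- cohort
    .fixture_env$report <- run_full(cohort)
  }
  .fixture_env$report
}

default_cohort <- function() {
  invisible(default_pipeline_report())
  .fixture_env$cohort
}

# a reduced cohort for cheap structural tests
small_cohort_spec <- function(seed = 20181008L) {
  cohort_spec(n_patients = c(GBM = 3L, meningioma = 3L),
              slices_per_patient = 1L,
              sequences = c("FLAIR", "T2W"),
              seed = seed)
}
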