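test_that("generated fields hit their target moments and determinism", {
  r1 <- generate_textured_roi(500, 50, 2, seed = 7)
  r2 <- generate_textured_roi(500, 50, 2, seed = 7)
  expect_identical(r1$pixels, r2$pixels)
  expect_identical(r1$mask, r2$mask)
  v <- roi_values(r1)
  expect_equal(mean(v), 500, tolerance = 1e-9)
  expect_equal(sd(v), 50, tolerance = 1e-9)
  expect_error(generate_textured_roi(0, 1, corr_len = 20, shape = c(32, 32)),
               "kernel")
})

test_that("white noise has near-zero lag-1 autocorrelation", {
  set.seed(201)
  r <- generate_textured_roi(0, 1, 0, shape = c(64L, 64L),
                             axes = c(28, 28))
  px <- r$pixels
  x <- as.vector(px[, -ncol(px)]); y <- as.vector(px[, -1])
  expect_lt(abs(cor(x, y)), 0.05)
})

test_that("smoothing lowers GLCM entropy at matched marginals", {
  set.seed(211)
  wins <- 0L
  for (i in 1:20) {
    sm <- generate_textured_roi(100, 10, 4, marginal = "exact")
    wh <- generate_textured_roi(100, 10, 0, marginal = "exact")
    ent <- function(r) {
      glcm_features(compute_glcm(quantize(r, 32L), 1, 0))[["GLCM_Entropy"]]
    }
    if (ent(sm) < ent(wh)) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("the exact marginal option pins the whole histogram", {
  set.seed(221)
  mk <- matrix(TRUE, 30, 30)
  a <- generate_textured_roi(10, 2, 3, shape = c(30L, 30L), mask = mk,
                             marginal = "exact")
  b <- generate_textured_roi(10, 2, 0, shape = c(30L, 30L), mask = mk,
                             marginal = "exact")
  expect_equal(sort(roi_values(a)), sort(roi_values(b)), tolerance = 1e-12)
})

test_that("the default cohort has the documented size and structure", {
  cohort <- default_cohort()
  rois <- cohort$rois
  expect_length(rois, 1000L)              # 500 per reader
  readers <- vapply(rois, function(r) r$meta$reader, character(1))
  expect_equal(sum(readers == "A"), 500L)
  expect_equal(sum(readers == "B"), 500L)
  # reader agreement on masks: Dice >= 0.8 on every generated pair
  expect_gte(cohort$ledger$reader_dice[["min"]], 0.8)
  # ledger declares the planted families
  expect_identical(cohort$ledger$planted_family[["GBM"]], "GLCM")
  expect_identical(cohort$ledger$planted_family[["meningioma"]], "HIST")
})

test_that("cohort generation is bit-reproducible under a fixed seed", {
  s <- small_cohort_spec()
  c1 <- generate_cohort(s)
  c2 <- generate_cohort(s)
  expect_identical(c1$rois[[1]]$pixels, c2$rois[[1]]$pixels)
  expect_identical(lapply(c1$rois, `[[`, "mask"),
                   lapply(c2$rois, `[[`, "mask"))
})

test_that("planted contrasts land where designed", {
  cohort <- default_cohort()
  spec <- cohort$spec
  meta <- lapply(cohort$rois, `[[`, "meta")
  pick <- function(disease, tissue, sequence, reader = "A") {
    sel <- vapply(meta, function(m) {
      m$disease == disease && m$tissue == tissue &&
        m$sequence == sequence && m$reader == reader
    }, logical(1))
    cohort$rois[sel]
  }
  # meningioma: >= 1 SD shift in the median intensity between tissues
  mt <- vapply(pick("meningioma", "tumor", "FLAIR"),
               function(r) pctl(roi_values(r), 0.5), numeric(1))
  me <- vapply(pick("meningioma", "edema", "FLAIR"),
               function(r) pctl(roi_values(r), 0.5), numeric(1))
  pooled_sd <- sqrt((var(mt) + var(me)) / 2)
  expect_gte(abs(mean(mt) - mean(me)) / pooled_sd, 1)
  # the shift sign follows the cohort configuration
  expect_equal(sign(mean(mt) - mean(me)), spec$shift_sign[["FLAIR"]])

  # GBM: matched means but a >= 1 SD GLCM correlation contrast
  gt <- pick("GBM", "tumor", "FLAIR"); ge <- pick("GBM", "edema", "FLAIR")
  mgt <- vapply(gt, function(r) mean(roi_values(r)), numeric(1))
  mge <- vapply(ge, function(r) mean(roi_values(r)), numeric(1))
  psd <- sqrt((var(mgt) + var(mge)) / 2)
  expect_lt(abs(mean(mgt) - mean(mge)) / max(psd, 1e-9), 0.1)
  corr1 <- function(r) {
    glcm_features(compute_glcm(quantize(r, 64L), 1, 0))[["GLCM_Correlation"]]
  }
  ct <- vapply(gt, corr1, numeric(1)); ce <- vapply(ge, corr1, numeric(1))
  csd <- sqrt((var(ct) + var(ce)) / 2)
  expect_gte(abs(mean(ct) - mean(ce)) / csd, 1)
})
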