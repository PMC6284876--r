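test_that("the documented 2x2 worked example is exact", {
  q <- as_qroi(list(levels = matrix(c(1, 1, 1, 2), 2, 2),
                    mask = matrix(TRUE, 2, 2), ng = 2L))
  g <- compute_glcm(q, 1, 0)
  expect_equal(g$p, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  expect_equal(sum(g$p), 1)
  f <- glcm_features(g)
  # contrast = sum (i-j)^2 p = 2 * 0.25; dissimilarity likewise
  expect_equal(f[["GLCM_Contrast"]], 0.5)
  expect_equal(f[["GLCM_Dissimilarity"]], 0.5)
})

test_that("constant and single-pixel inputs hit the documented edges", {
  qc <- as_qroi(list(levels = matrix(1L, 3, 3), mask = matrix(TRUE, 3, 3),
                     ng = 1L))
  g <- compute_glcm(qc, 1, 0)
  expect_equal(g$p[1, 1], 1)
  f <- glcm_features(g)
  expect_equal(f[["GLCM_Energy"]], 1)
  expect_equal(f[["GLCM_Entropy"]], 0)
  expect_equal(f[["GLCM_Contrast"]], 0)
  expect_equal(f[["GLCM_MaxProbability"]], 1)

  mk <- matrix(FALSE, 3, 3); mk[2, 2] <- TRUE
  lev <- matrix(0L, 3, 3); lev[2, 2] <- 1L
  q1 <- as_qroi(list(levels = lev, mask = mk, ng = 1L))
  g1 <- compute_glcm(q1, 1, 0)
  expect_true(g1$empty)
  f1 <- glcm_features(g1)
  expect_length(feature_undefined(f1), 22L)
})

test_that("uniform matrices give the closed-form entropy and energy", {
  for (n in c(2L, 4L, 8L)) {
    g <- structure(list(p = matrix(1 / n^2, n, n), d = 1L, theta = 0L,
                        n_pairs = n^2, empty = FALSE), class = "glcm")
    f <- glcm_features(g)
    expect_equal(f[["GLCM_Entropy"]], 2 * log2(n), tolerance = 1e-12)
    expect_equal(f[["GLCM_Energy"]], 1 / n^2, tolerance = 1e-12)
  }
})

test_that("compute_glcm matches the brute-force pair enumerator exactly", {
  set.seed(71)
  for (rep in 1:60) {
    im <- random_masked_image(sample(3:12, 1), sample(3:12, 1),
                              sample(2:8, 1))
    q <- as_qroi(im)
    for (d in 1:5) {
      for (th in c(0, 45, 90, 135)) {
        oracle <- oracle_glcm_counts(im$levels, im$mask, d, th)
        # pad oracle to the full level range
        cnt <- matrix(0L, im$ng, im$ng)
        cnt[seq_len(nrow(oracle)), seq_len(ncol(oracle))] <- oracle
        g <- compute_glcm(q, d, th)
        if (sum(cnt) == 0) {
          expect_true(g$empty)
        } else {
          sym <- cnt + t(cnt)
          expect_equal(g$n_pairs, sum(cnt))
          expect_equal(round(g$p * sum(sym)), sym,
                       ignore_attr = TRUE)
        }
      }
    }
  }
})

test_that("sum average equals twice the marginal mean on symmetric matrices", {
  set.seed(81)
  for (i in 1:20) {
    im <- random_masked_image(10, 10, 6)
    g <- compute_glcm(as_qroi(im), 1, 45)
    if (g$empty) next
    f <- glcm_features(g)
    marg_mean <- sum(seq_len(6) * rowSums(g$p))
    expect_equal(f[["GLCM_SumAverage"]], 2 * marg_mean, tolerance = 1e-12)
  }
})

test_that("the feature block emits 440 uniquely named features", {
  set.seed(91)
  roi <- roi_from_matrix(matrix(rnorm(64), 8, 8))
  blk <- glcm_feature_block(quantize(roi, 8L))
  expect_length(blk, 22L * 20L)
  expect_false(anyDuplicated(names(blk)) > 0)
  expect_match(names(blk)[1], "^GLCM_.*_d1_a000$")
})

test_that("a 90-degree-symmetric image yields equal 0/90-degree features", {
  # image invariant under transposition
  m <- matrix(c(1, 2, 3, 2, 1, 2, 3, 2, 1), 3, 3)
  q <- quantize(roi_from_matrix(m), 3L)
  f0 <- glcm_features(compute_glcm(q, 1, 0))
  f90 <- glcm_features(compute_glcm(q, 1, 90))
  expect_equal(as.numeric(f0), as.numeric(f90), tolerance = 1e-12)
})

test_that("GLCM features are invariant under affine intensity maps", {
  set.seed(101)
  px <- matrix(rnorm(144, 10, 3), 12, 12)
  b1 <- glcm_feature_block(quantize(roi_from_matrix(px), 16L),
                           distances = 1:2, angles = c(0, 90))
  b2 <- glcm_feature_block(quantize(roi_from_matrix(0.5 * px - 40), 16L),
                           distances = 1:2, angles = c(0, 90))
  expect_equal(as.numeric(b1), as.numeric(b2), tolerance = 1e-12)
})
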