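test_that("roc_auc reproduces the hand-enumerated pair counts", {
  r1 <- roc_auc(c(1, 2, 3), c(0, 1, 1))
  expect_equal(r1$auc, 1.0)
  r2 <- roc_auc(c(1, 2, 2), c(0, 1, 0))
  expect_equal(r2$auc, 0.75)
  expect_equal(r2$auc, oracle_auc(c(1, 2, 2), c(0, 1, 0)))
})

test_that("roc_auc equals the brute-force pair count on random vectors", {
  set.seed(151)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    y <- c(0L, 1L, rbinom(n - 2L, 1L, 0.5))
    s <- sample(1:8, n, replace = TRUE)    # heavy ties on purpose
    got <- roc_auc(s, y)
    want <- oracle_auc(s, y)
    want_oriented <- max(want, 1 - want)
    expect_equal(got$auc, want_oriented, tolerance = 1e-12)
    expect_identical(got$direction,
                     if (want >= 0.5) "greater_is_tumor" else "less_is_tumor")
    expect_true(got$ci_low <= got$auc + 1e-12)
    expect_true(got$ci_high >= got$auc - 1e-12)
  }
})

test_that("degenerate and error cases follow the contract", {
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  tied <- roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(tied$auc, 0.5)
  expect_true(tied$degenerate)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(161)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0L, 1L)
  a1 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a1, tolerance = 1e-12)
  expect_equal(roc_auc(qnorm(plogis(s)), y)$auc, a1, tolerance = 1e-9)
})

test_that("permutation null is centered at 0.5", {
  set.seed(171)
  s <- rnorm(400)
  y <- rep(c(0L, 1L), 200)
  inside <- 0L
  for (i in 1:100) {
    a <- roc_auc(s, sample(y))$auc
    if (abs(a - 0.5) <= 0.1) inside <- inside + 1L
  }
  expect_gte(inside, 95L)
})

test_that("perfect thresholds appear exactly when class ranges are disjoint", {
  r <- find_perfect_threshold(c(1, 2, 5, 6), c(1, 1, 0, 0))
  expect_true(r$perfect)
  expect_identical(r$direction, "<")
  expect_equal(r$cut, 3.5)

  r2 <- find_perfect_threshold(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_true(r2$perfect)
  expect_identical(r2$direction, ">")
  expect_equal(r2$cut, 3.5)

  expect_null(find_perfect_threshold(rep(4, 6), rep(c(0, 1), 3)))

  # overlapping values: best-accuracy cut, verified by exhaustive scan
  set.seed(181)
  for (i in 1:30) {
    v <- sample(1:10, 12, replace = TRUE)
    y <- rbinom(12, 1, 0.5); y[1:2] <- c(0L, 1L)
    r3 <- find_perfect_threshold(v, y)
    if (is.null(r3)) next
    u <- sort(unique(v))
    cuts <- (u[-1] + u[-length(u)]) / 2
    best <- 0
    for (cut in cuts) {
      best <- max(best, mean((v < cut) == y), mean((v > cut) == y))
    }
    expect_equal(r3$accuracy, best)
    expect_identical(r3$perfect, max(v[y == 1]) < min(v[y == 0]) ||
                       min(v[y == 1]) > max(v[y == 0]))
  }
})

test_that("kappa matches the closed form and the degenerate rule", {
  # identical mixed sequences agree perfectly
  lab <- c("tumor", "edema", "tumor", "tumor", "edema")
  expect_equal(cohens_kappa(lab, lab), 1)

  # printed 2x2 worked example: a=20, b=5, c=10, d=15
  a_lab <- c(rep(1, 25), rep(0, 25))
  b_lab <- c(rep(1, 20), rep(0, 5), rep(1, 10), rep(0, 15))
  expect_equal(cohens_kappa(a_lab, b_lab), 0.4)

  # cross-check against an independent implementation
  expect_equal(cohens_kappa(a_lab, b_lab),
               e1071::classAgreement(table(a_lab, b_lab))$kappa,
               tolerance = 1e-12)

  # both raters constant: kappa 1 on agreement, 0 otherwise
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5)), 1)
  expect_equal(cohens_kappa(rep(1, 5), rep(0, 5)), 0)
  expect_error(cohens_kappa(1:3, 1:4), "lengths differ")
})

test_that("independent random labels give kappa near zero", {
  set.seed(191)
  a <- rbinom(1000, 1, 0.5)
  b <- rbinom(1000, 1, 0.5)
  expect_lt(abs(cohens_kappa(a, b)), 0.1)
})

test_that("scenario evaluation renders NA rows and model AUC identities", {
  rep <- default_pipeline_report()
  s <- rep$evaluation$summary
  # every scenario of the grid appears exactly once
  expect_equal(nrow(s), 2L * 2L * 5L)
  expect_false(anyDuplicated(s[c("disease", "normalization", "sequence")]) > 0)
  # no-agreement rows render NA
  na_rows <- s[s$status %in% c("no_agreement", "none_selected"), ]
  expect_true(all(is.na(na_rows$auc)))
  # single-feature consensus: model AUC equals the univariate AUC
  one <- s[s$status == "ok" &
             !grepl(";", s$parameters, fixed = TRUE), ]
  if (nrow(one) > 0) expect_equal(one$model_auc, one$auc, tolerance = 1e-12)
})
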