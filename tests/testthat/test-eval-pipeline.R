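test_that("robust-PCA outlier detection removes the planted contamination", {
  expect_equal(detectOutliersRobustPCA(matrix(rnorm(50), 10), 0), rep(TRUE, 10))

  set.seed(31)
  x <- matrix(rnorm(100 * 8), 100)
  expect_equal(sum(detectOutliersRobustPCA(x, 0.2, seed = 1)), 80L)

  # 95 clean rows + 5 rows shifted by 10 sigma: all five are flagged
  set.seed(32)
  m <- rbind(matrix(rnorm(95 * 10), 95), matrix(rnorm(5 * 10, mean = 10), 5))
  mask <- detectOutliersRobustPCA(m, 0.05, seed = 2)
  expect_equal(which(!mask), 96:100)

  expect_error(detectOutliersRobustPCA(m, 1), "reductionFactor")
})

test_that("temporal split keeps event order and tail prevalence", {
  y <- c(rep(0L, 88), rep(1L, 12))   # positives cluster late in the season
  tbl <- featureTable(matrix(rnorm(200), 100), y)
  sp <- temporalSplit(tbl, 0.8)
  expect_equal(nrow(featureMatrix(sp$train)), 80L)
  expect_equal(nrow(featureMatrix(sp$test)), 20L)
  expect_lte(max(sampleInfo(sp$train)$event_index),
             min(sampleInfo(sp$test)$event_index))
  expect_equal(mean(featureLabels(sp$test)), mean(y[81:100]))

  shuffled <- featureTable(matrix(rnorm(20), 10), rep(0:1, 5),
                           samples = data.frame(player_id = "a",
                                                event_index = c(5L, 1L, 2:4, 6:10)))
  expect_error(temporalSplit(shuffled), "not ordered")
})

test_that("SMOTE balances classes with synthetics on minority segments", {
  set.seed(33)
  x <- rbind(matrix(rnorm(40 * 3), 40), matrix(rnorm(8 * 3, 4), 8))
  y <- c(rep(0L, 40), rep(1L, 8))
  tbl <- featureTable(x, y)
  bal <- oversampleSMOTE(tbl, kNeighbors = 5L, seed = 3L)
  yb <- featureLabels(bal)
  expect_equal(sum(yb == 1L), sum(yb == 0L))
  expect_equal(nrow(featureMatrix(bal)), 80L)
  # originals preserved as the leading rows
  expect_equal(featureMatrix(bal)[1:48, ], featureMatrix(tbl),
               ignore_attr = TRUE)

  # two minority points, k = 1: synthetics lie on the connecting segment
  x2 <- rbind(matrix(rnorm(20 * 2, 10), 20), c(0, 0), c(1, 1))
  y2 <- c(rep(0L, 20), 1L, 1L)
  bal2 <- oversampleSMOTE(featureTable(x2, y2), kNeighbors = 1L, seed = 4L)
  syn <- featureMatrix(bal2)[-(1:22), , drop = FALSE]
  expect_equal(syn[, 1], syn[, 2], tolerance = 1e-12)
  expect_true(all(syn >= 0 & syn <= 1))

  # deterministic under a fixed seed
  balA <- oversampleSMOTE(tbl, seed = 9L)
  balB <- oversampleSMOTE(tbl, seed = 9L)
  expect_identical(featureMatrix(balA), featureMatrix(balB))

  expect_error(oversampleSMOTE(featureTable(x2, y2), kNeighbors = 5L),
               "smaller kNeighbors")
})

test_that("PCA reduction is train-only and meets the variance threshold", {
  # data exactly in a 2-d subspace of 5-d
  set.seed(34)
  basis <- qr.Q(qr(matrix(rnorm(10), 5)))[, 1:2]
  z <- matrix(rnorm(60 * 2), 60)
  x <- z %*% t(basis)
  tbl <- featureTable(x, rbinom(60, 1, 0.3))
  red <- pcaReduce(tbl, tbl, 0.95)
  expect_equal(red$nComponents, 2L)
  expect_equal(sum(red$explainedVariance[1:2]), 1, tolerance = 1e-10)

  # threshold 1 keeps the full rank
  xr <- matrix(rnorm(40 * 4), 40)
  tblr <- featureTable(xr, rbinom(40, 1, 0.4))
  expect_equal(pcaReduce(tblr, tblr, 1)$nComponents, 4L)

  # spectrum equals the eigendecomposition of the train covariance
  ev <- eigen(cov(xr), symmetric = TRUE)$values
  expect_equal(pcaReduce(tblr, tblr, 1)$explainedVariance,
               ev / sum(ev), tolerance = 1e-8)

  # leakage guard: a covariance-shifting test set must not alter the
  # transform fitted on train alone
  testShift <- featureTable(xr + 50, rbinom(40, 1, 0.4))
  redA <- pcaReduce(tblr, tblr, 0.95)
  redB <- pcaReduce(tblr, testShift, 0.95)
  expect_identical(featureMatrix(redA$train), featureMatrix(redB$train))

  expect_error(pcaReduce(tblr, tblr, 1.2), "varianceThreshold")
})

test_that("repeated stratified CV preserves class ratio and is deterministic", {
  set.seed(35)
  x <- matrix(rnorm(60 * 3), 60)
  y <- c(rep(1L, 21), rep(0L, 39))
  tbl <- featureTable(x, y)
  cv <- crossValidate(tbl, modelSpec("LDA"), repeats = 10L, folds = 2L,
                      seed = 8L)
  expect_equal(nrow(cv$validation), 20L)
  expect_equal(nrow(cv$training), 20L)

  # fold balance: positives per fold within 1 of the proportional share
  for (r in 1:10) {
    set.seed(8L + r)
    fold <- fwfoot:::.stratifiedFolds(y, 2L)
    for (f in 1:2)
      expect_lte(abs(sum(y[fold == f]) - sum(y) / 2), 1)
  }

  cv2 <- crossValidate(tbl, modelSpec("LDA"), repeats = 10L, folds = 2L,
                       seed = 8L)
  expect_identical(cv, cv2)

  expect_error(crossValidate(featureTable(x, rep(0L, 60)), modelSpec("LDA")),
               "positive")

  sm <- summarizeMetrics(cv$validation)
  expect_true(all(sm$low <= sm$mean & sm$mean <= sm$high))
})

test_that("every classifier family returns usable scores and separates signal", {
  set.seed(36)
  n <- 80
  x <- matrix(rnorm(n * 4), n)
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(n, sd = 0.5) > 0.8)
  tr <- 1:60; te <- 61:80
  for (fam in c("LDA", "LR", "NB", "KNN", "SVM", "CART", "RF", "MLP")) {
    sc <- fitPredict(modelSpec(fam, seed = 2L), x[tr, ], y[tr], x[te, ])
    expect_length(sc, 20L)
    expect_true(all(is.finite(sc)), info = fam)
    auc <- computeMetrics(sc, y[te])["roc_auc"]
    expect_gt(auc, 0.5)
    # stochastic families are reproducible under the recorded seed
    sc2 <- fitPredict(modelSpec(fam, seed = 2L), x[tr, ], y[tr], x[te, ])
    expect_identical(sc, sc2, info = fam)
  }
  expect_error(fitPredict(modelSpec("LDA"), x[tr, ], rep(0L, 60), x[te, ]),
               "both classes")
})

test_that("permutation p-values hit the analytic extremes", {
  # observed above every null draw: p = 1 / (n + 1)
  x <- matrix(c(rep(0, 30), rep(10, 10)), ncol = 1)
  y <- c(rep(0L, 30), rep(1L, 10))
  sepPipe <- function(x, y) computeMetrics(x[, 1], y)[["roc_auc"]]
  pt <- permutationTest(sepPipe, featureTable(x, y), nPermutations = 49L,
                        seed = 1L)
  expect_equal(pt$p.value, 1 / 50)
  expect_length(pt$null, 49L)

  # observed below every null: p = 1
  ptW <- permutationTest(function(x, y) if (all(y == sort(y))) -1 else 1,
                         featureTable(x, y), nPermutations = 19L, seed = 1L)
  expect_equal(ptW$p.value, 1)
  expect_error(permutationTest(sepPipe, featureTable(x, y), 0L), "nPermutations")
})

test_that("bias-variance terms behave for degenerate learners", {
  set.seed(37)
  # heavily imbalanced training data: a default CART collapses to the
  # majority class and becomes a constant learner
  xtr <- matrix(rnorm(100 * 2), 100)
  ytr <- c(rep(1L, 20), rep(0L, 80))
  xte <- matrix(rnorm(40 * 2), 40)
  yte <- c(rep(1L, 10), rep(0L, 30))
  bv <- biasVarianceDecompose(modelSpec("CART", list(cp = 1)),
                              featureTable(xtr, ytr), featureTable(xte, yte),
                              nBootstrap = 50L, seed = 5L)
  expect_equal(bv$variance, 0)
  expect_equal(bv$bias, mean(yte))
  expect_true(all(c(bv$expected_loss, bv$bias, bv$variance) >= 0) &&
                all(c(bv$expected_loss, bv$bias, bv$variance) <= 1))
  expect_equal(bv$expected_loss, mean(bv$losses), tolerance = 1e-12)
})
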