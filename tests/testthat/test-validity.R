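test_that("permutation test reports the original model last, leaves X untouched", {
  sim <- simulateExtractStudy(seed = 9)
  Xs <- uvScale(sim$mset)
  y <- activities(sim$mset)$inv_agi
  before <- Xs@values + 0   # force a copy
  pt <- permutationTest(Xs, y, "PLS", nComponents = 1, nPerm = 5, seed = 2)
  expect_identical(Xs@values, before)
  expect_identical(nrow(pt$runs), 6L)
  orig <- pt$runs[6, ]
  expect_equal(orig$correlation, 1)
  m <- fitProjection(Xs, y, "PLS", nComponents = 1)
  expect_equal(orig$r2y, r2y(m), tolerance = 1e-10)
  expect_equal(orig$q2, modelQ2(m), tolerance = 1e-10)
  expect_error(permutationTest(Xs, y, "PLS", 1, nPerm = 1), "nPerm")
})

test_that("permuted fits decay: Q2 intercept is negative under planted signal", {
  neg <- logical(10)
  for (s in seq_len(10)) {
    sim <- simulateExtractStudy(seed = 20 + s)
    Xs <- uvScale(sim$mset)
    pt <- permutationTest(Xs, activities(sim$mset)$inv_agi, "PLS",
                          nComponents = 1, nPerm = 20, seed = s)
    neg[s] <- pt$q2Intercept < 0
  }
  expect_gte(mean(neg), 0.9)
})

test_that("CV-ANOVA degenerates to p = 1 exactly when the model cannot beat the mean", {
  # consistency: Q2 <= 0 (PRESS >= SS) forces F = 0 and p = 1
  set.seed(31)
  found <- 0
  for (i in 1:10) {
    X <- scale(matrix(rnorm(24 * 15), 24, 15))
    y <- rnorm(24)
    q <- q2CV(X, y, "PLS", nComponents = 1)
    p <- cvAnova(X, y, "PLS", nComponents = 1)
    expect_gte(p, 0); expect_lte(p, 1)
    if (q <= 0) { found <- found + 1; expect_identical(p, 1) }
  }
  expect_gt(found, 0)
})

test_that("CV-ANOVA detects the planted signal", {
  hit <- logical(10)
  for (s in seq_len(10)) {
    sim <- simulateExtractStudy(seed = 40 + s)
    Xs <- uvScale(sim$mset)
    hit[s] <- cvAnova(Xs, activities(sim$mset)$inv_agi, "PLS",
                      nComponents = 1) < 0.05
  }
  expect_gte(mean(hit), 0.95)
})

test_that("the validity rule combines the four criteria and is monotone", {
  th <- validityThresholds()
  # the published worked row: diff .178, intercepts .261/-.478, two p-values
  expect_true(isValidModel(0.178, 0.261, -0.478, c(0.00142708, 0.00210300), th))
  expect_false(isValidModel(0.35, 0.261, -0.478, c(0.001, 0.002), th))
  expect_false(isValidModel(0.178, 0.261, 0.06, c(0.001, 0.002), th))
  expect_false(isValidModel(0.178, 0.261, -0.478, c(0.001, 0.06), th))
  # worsening any single criterion never flips invalid -> valid
  base <- c(diff = 0.2, r2i = 0.3, q2i = -0.1, p = 0.01)
  worse <- list(c(0.4, 0.3, -0.1, 0.01), c(0.2, 0.5, -0.1, 0.01),
                c(0.2, 0.3, 0.1, 0.01), c(0.2, 0.3, -0.1, 0.2))
  for (w in worse)
    expect_false(isValidModel(w[1], w[2], w[3], w[4], th) &&
                   !isValidModel(base[1], base[2], base[3], base[4], th))
})

test_that("the gate reports one row per supervised model with coherent flags", {
  sim <- simulateExtractStudy(seed = 5)
  g <- validityGate(sim$mset, seed = 5)
  expect_identical(nrow(g), 24L)          # all but PCA
  expect_false("M1" %in% g$model)
  expect_identical(g$diff, g$r2y - g$q2)
  recheck <- mapply(function(d, r2i, q2i, i) isValidModel(d, r2i, q2i,
                                                          g$cvAnovaPerTarget[[i]]),
                    g$diff, g$r2Intercept, g$q2Intercept, seq_len(nrow(g)))
  expect_identical(unname(recheck), g$valid)
  expect_gt(sum(g$valid), 0)              # planted signal validates models
})
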