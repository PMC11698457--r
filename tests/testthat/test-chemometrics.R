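test_that("first PLS weight equals the closed form X'y/||X'y|| on random instances", {
  set.seed(21)
  for (i in 1:5) {
    X <- scale(matrix(rnorm(60), 10, 6))
    y <- rnorm(10)
    m <- fitProjection(X, y, "PLS", nComponents = 1)
    wref <- crossprod(X, scale(y)[, 1])
    wref <- wref / sqrt(sum(wref^2))
    expect_lt(max(abs(abs(xWeights(m)[, 1]) - abs(wref))), 1e-8)
  }
})

test_that("noiseless linear response is fully explained at the generating rank", {
  set.seed(22)
  X <- scale(matrix(rnorm(40 * 6), 40, 6))
  B <- rnorm(6)
  y <- X %*% B           # exact linear map, no noise
  m <- fitProjection(X, y, "PLS", nComponents = 6)
  expect_gt(r2y(m), 1 - 1e-8)
  expect_gt(modelQ2(m), 0.99)   # perfectly predictable under CV
})

test_that("OPLS with 1 predictive + a orthogonal components fits like PLS with a+1", {
  set.seed(23)
  for (a in 1:3) {
    X <- scale(matrix(rnorm(20 * 10), 20, 10))
    y <- X[, 1] + 0.5 * X[, 2] + rnorm(20, 0, 0.3)
    mo <- fitProjection(X, y, "OPLS", nComponents = 1, nOrth = a)
    mp <- fitProjection(X, y, "PLS", nComponents = a + 1)
    expect_lt(max(abs(predictY(mo, X) - predictY(mp, X))), 1e-6)
  }
})

test_that("scores are orthogonal and Q2 never exceeds R2Y on synthetic fixtures", {
  for (s in 1:3) {
    sim <- simulateExtractStudy(seed = s)
    Xs <- uvScale(sim$mset)
    for (method in c("PLS", "OPLS")) {
      m <- fitProjection(Xs, activities(sim$mset)$inv_agi, method,
                         nComponents = if (method == "PLS") 3 else 1,
                         nOrth = if (method == "OPLS") 2 else NULL)
      Tm <- cbind(scores(m), orthoScores(m))
      g <- crossprod(Tm)
      expect_lt(max(abs(g[upper.tri(g)])), 1e-8 * max(diag(g)))
      expect_lte(modelQ2(m), r2y(m) + 1e-8)
    }
  }
})

test_that("PCA reproduces the eigenstructure of the correlation matrix", {
  set.seed(25)
  X <- scale(matrix(rnorm(30 * 8), 30, 8))
  m <- fitProjection(X, method = "PCA", nComponents = 5)
  ev <- eigen(cor(X))$values
  compVar <- colSums(scores(m)^2) / (nrow(X) - 1)
  expect_lt(max(abs(compVar - ev[1:5])), 1e-6)
})

test_that("requesting more components than the rank names the achievable rank", {
  X <- scale(matrix(rnorm(12), 4, 3))    # rank 3
  expect_error(fitProjection(X, rnorm(4), "PLS", nComponents = 5),
               "achievable rank 3")
})

test_that("VIP matches the analytic toy case and its normalization identity", {
  # p=2, single component, w = (1, 0) -> VIP = (sqrt(2), 0); force it with
  # a y depending only on feature 1 and orthogonal features
  X <- scale(matrix(c(1, -1, 2, -2, 1, 1, -1, -1), 4, 2))
  y <- X[, 1]
  m <- fitProjection(X, y, "PLS", nComponents = 1)
  expect_lt(max(abs(vip(m) - c(sqrt(2), 0))), 1e-8)

  set.seed(26)
  for (i in 1:4) {
    Xr <- scale(matrix(rnorm(18 * 7), 18, 7))
    yr <- cbind(rnorm(18), rnorm(18))
    mr <- fitProjection(Xr, yr, "PLS", nComponents = 3)
    expect_lt(abs(mean(vip(mr)^2) - 1), 1e-8)
  }

  # duplicated feature columns get equal VIP
  Xd <- scale(cbind(a = rnorm(15), b = rnorm(15)))
  Xd <- cbind(Xd, c = Xd[, "a"])
  yd <- rnorm(15)
  md <- fitProjection(Xd, yd, "PLS", nComponents = 1)
  expect_lt(abs(vip(md)["a"] - vip(md)["c"]), 1e-8)

  mpca <- fitProjection(scale(matrix(rnorm(20), 5, 4)), method = "PCA")
  expect_error(vip(mpca), "PCA")
})

test_that("activity direction follows the score-target correlation sign", {
  sim <- simulateExtractStudy(seed = 7)
  Xs <- uvScale(sim$mset)
  m <- fitProjection(Xs, activities(sim$mset)$inv_agi, "PLS", nComponents = 2)
  t1 <- scores(m)[, 1]
  expect_identical(activityDirection(m, t1)[1], 1)
  expect_identical(activityDirection(m, -t1)[1], -1)
  expect_error(activityDirection(m, rep(1, 30)), "zero variance")
})

test_that("top-feature selection ranks by oriented loading, filters by VIP, and is sign-stable", {
  # hand-ranked toy: direction negative on comp 1, oriented-loading order
  # f1 before f3, middling feature f2 filtered out by VIP <= 1.
  # Features carry (0.95, 0.1, 0.75) of the latent t1 with complementary
  # noise so the scaled loadings keep that order.
  set.seed(27)
  n <- 400
  t1 <- rnorm(n)
  X <- scale(cbind(f1 = -(0.95 * t1 + sqrt(1 - 0.95^2) * rnorm(n)),
                   f2 = 0.10 * t1 + sqrt(1 - 0.10^2) * rnorm(n),
                   f3 = -(0.75 * t1 + sqrt(1 - 0.75^2) * rnorm(n))))
  y <- -t1                       # activity decreases along t1
  m <- fitProjection(X, y, "PLS", nComponents = 1)
  expect_identical(selectTopFeatures(m, y, k = 2), c("f1", "f3"))

  # VIP filter exhaustion -> empty list
  expect_identical(selectTopFeatures(m, y, k = 2, vipMin = 10), character(0))

  # flipping the component sign flips the direction but not the selection
  sim <- simulateExtractStudy(seed = 8)
  Xs <- uvScale(sim$mset)
  act <- activities(sim$mset)$inv_agi
  m1 <- fitProjection(Xs, act, "PLS", nComponents = 1)
  m2 <- m1
  m2@W <- -m2@W; m2@P <- -m2@P; m2@C <- -m2@C; m2@scores <- -m2@scores
  expect_identical(selectTopFeatures(m1, act), selectTopFeatures(m2, act))

  # feature-column order does not change the selected set
  perm <- sample(ncol(Xs@values))
  mP <- fitProjection(Xs@values[, perm], act, "PLS", nComponents = 1)
  expect_setequal(selectTopFeatures(mP, act), selectTopFeatures(m1, act))
})

test_that("planted actives dominate the PLS top-25 across seeds", {
  hit <- numeric(20)
  for (s in seq_len(20)) {
    sim <- simulateExtractStudy(seed = s)
    Xs <- uvScale(sim$mset)
    act <- activities(sim$mset)$inv_agi
    m <- fitProjection(Xs, act, "PLS")
    hit[s] <- mean(sim$truth$activeSet %in% selectTopFeatures(m, act))
  }
  expect_gte(mean(hit), 0.9)
})

test_that("the 25-model table matches the published suite structure", {
  tab <- modelTable()
  expect_identical(nrow(tab), 25L)
  expect_identical(tab$method[1], "PCA")
  expect_identical(sum(tab$da), 12L)
  expect_identical(tab["M8", "method"], "OPLS")
  expect_identical(tab["M8", "y"][[1]], c("inv_agi", "inv_dpph"))
  expect_identical(tab["M22", "y"][[1]], "ic50_dpph")
})
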