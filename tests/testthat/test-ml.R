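test_that("performance metrics match their defining formulas", {
  rmse <- mzConsensus:::.rmse
  r2 <- mzConsensus:::.r2
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 5), c(1, 2, 3)), sqrt(4 / 3))
  expect_identical(r2(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(4, 7, 1, 8)
  expect_lt(abs(r2(obs, rep(mean(obs), 4))), 1e-10)  # mean prediction -> 0
})

test_that("stratified bootstrap keeps stratum proportions, provenance and determinism", {
  sim <- simulateExtractStudy(seed = 2)
  aug <- bootstrapAugment(sim$mset, nOut = 50, seed = 3)
  expect_identical(nrow(sampleMeta(aug)), 50L)
  expect_identical(as.integer(table(sampleMeta(aug)$ethanol_pct)), rep(10L, 5))
  expect_true(all(sampleMeta(aug)$source_id %in% sampleMeta(sim$mset)$sample_id))
  # with replacement: drawing n rows still can duplicate
  aug30 <- bootstrapAugment(sim$mset, nOut = 30, seed = 4)
  expect_gt(anyDuplicated(sampleMeta(aug30)$source_id), 0)
  expect_identical(sampleMeta(bootstrapAugment(sim$mset, 50, seed = 3)),
                   sampleMeta(aug))
  expect_false(identical(sampleMeta(bootstrapAugment(sim$mset, 50, seed = 5)),
                         sampleMeta(aug)))
})

test_that("splitting before augmenting keeps bootstrap copies out of the test set", {
  sim <- simulateExtractStudy(seed = 2)
  split <- splitData(30, 0.5, seed = 1)
  aug <- bootstrapAugment(sim$mset[, split$train], nOut = 50, seed = 2)
  trainIds <- sampleMeta(sim$mset)$sample_id[split$train]
  testIds <- sampleMeta(sim$mset)$sample_id[split$test]
  expect_true(all(sampleMeta(aug)$source_id %in% trainIds))
  expect_false(any(sampleMeta(aug)$source_id %in% testIds))
  expect_warning(compareModels(sim$mset, methods = "random_forest",
                               augment = TRUE, order = "augment_then_split"),
                 "train and test")
})

test_that("tree models learn and predict deterministically", {
  set.seed(51)
  X <- matrix(runif(200), 40, 5); colnames(X) <- paste0("Var0", 1:5)
  y <- 3 * X[, 1] + rnorm(40, 0, 0.1)
  for (meth in c("decision_tree", "random_forest", "gradient_boosting",
                 "ada_boost", "linear_regression")) {
    m <- trainModel(mlConfig(meth), X, y, seed = 7)
    pr <- predictModel(m, X)
    expect_true(all(is.finite(pr)))
    expect_gt(cor(pr, y), 0.8)
    m2 <- trainModel(mlConfig(meth), X, y, seed = 7)
    expect_identical(predictModel(m2, X), pr)
  }
})

test_that("random forest beats the single tree on held-out data (20 seeds)", {
  sim <- simulateExtractStudy(seed = 3)
  wins <- logical(20)
  for (s in seq_len(20)) {
    perf <- compareModels(sim$mset, methods = c("decision_tree", "random_forest"),
                          seed = s)
    wins[s] <- perf$rmseTest[perf$method == "random_forest"] <=
      perf$rmseTest[perf$method == "decision_tree"]
  }
  expect_gte(mean(wins), 0.8)
})

test_that("permutation importance is exactly zero for unused or constant features", {
  stump <- make_stump()            # splits on Var01 only
  X <- stump$trainX; y <- stump$trainY
  X <- cbind(X, Var03 = rep(2, nrow(X)))   # constant extra column
  pi_ <- permutationImportance(stump, X, y, nPerm = 30, seed = 1)
  expect_identical(pi_$score[pi_$var_id == "Var02"], 0)
  expect_identical(pi_$score[pi_$var_id == "Var03"], 0)
  expect_gt(pi_$score[pi_$var_id == "Var01"], 0)
})

test_that("permutation importance matches the exhaustive-permutation average at small n", {
  stump <- make_stump(n = 6)
  X <- stump$trainX; y <- stump$trainY
  base <- mzConsensus:::.rmse(y, predictModel(stump, X))
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) all(sort(r) == 1:6)), ]
  exact <- mean(apply(perms, 1, function(pr) {
    Xp <- X; Xp[, 1] <- X[pr, 1]
    mzConsensus:::.rmse(y, predictModel(stump, Xp)) - base
  }))
  est <- permutationImportance(stump, X, y, nPerm = 3000, seed = 2)
  expect_lt(abs(est$score[est$var_id == "Var01"] - exact), 0.05 * exact)
})

test_that("Shapley attributions satisfy the stump closed form and local accuracy", {
  stump <- make_stump()
  X <- stump$trainX
  sh <- shapleyScores(stump, X)
  pred <- predictModel(stump, X)
  expect_lt(max(abs(sh$phi[, 2])), 1e-12)              # untouched feature
  expect_equal(sh$phi[, 1], pred - mean(pred), tolerance = 1e-10)
  expect_equal(rowSums(sh$phi) + sh$base, pred, tolerance = 1e-10)
  expect_error(shapleyScores(trainModel(mlConfig("linear_regression"),
                                        X, stump$trainY), X),
               "tree models")
})

test_that("Shapley values equal brute-force coalition enumeration on small forests", {
  set.seed(53)
  n <- 14; p <- 6
  X <- matrix(runif(n * p), n, p); colnames(X) <- paste0("Var0", 1:p)
  y <- 2 * X[, 1] - 3 * X[, 2] + X[, 3] * X[, 4] + rnorm(n, 0, 0.05)
  rf <- trainModel(mlConfig("random_forest", nTrees = 10), X, y, seed = 3)
  sh <- shapleyScores(rf, X[1:3, , drop = FALSE], background = X)
  for (i in 1:3) {
    oracle <- brute_shapley(rf, X[i, ], X)
    expect_equal(unname(sh$phi[i, ]), oracle, tolerance = 1e-8)
  }
})

test_that("duplicated feature columns share Shapley credit symmetrically", {
  set.seed(54)
  n <- 20
  a <- runif(n)
  X <- cbind(Var01 = a, Var02 = a, Var03 = runif(n))
  y <- 4 * a + rnorm(n, 0.05)
  rf <- trainModel(mlConfig("random_forest", nTrees = 60), X, y, seed = 4)
  sh <- shapleyScores(rf, X)
  expect_equal(sh$score[["Var01"]], sh$score[["Var02"]],
               tolerance = 0.25 * sh$score[["Var01"]])
})

test_that("correlation ranking and sign screening follow the documented rules", {
  set.seed(55)
  x1 <- rnorm(12)
  X <- cbind(A = x1, B = -x1 + rnorm(12, 0, 0.01), C = rnorm(12))
  y <- 2 * x1
  cr <- correlationRanking(X, y, k = 2)
  expect_identical(cr$entries$var_id[1], "A")
  expect_equal(cr$correlations[["A"]], 1, tolerance = 1e-12)
  expect_lt(cr$correlations[["B"]], -0.99)
  expect_false("B" %in% cr$entries$var_id)
  expect_error(correlationRanking(X, rep(1, 12)), "constant target")

  # hand-computed toy correlations and ranks
  Xt <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 3, 2, 4))
  yt <- c(2, 4, 6, 8)
  crt <- correlationRanking(Xt, yt, k = 3)
  expect_identical(crt$entries$var_id, c("a", "c", "b"))
  expect_equal(unname(crt$correlations), c(1, -1, 0.8), tolerance = 1e-12)

  lst <- data.frame(var_id = c("A", "B"), score = c(2, 1))
  sc <- signScreen(lst, cr$correlations)
  expect_identical(sc$var_id, "A")
  expect_identical(signScreen(sc, cr$correlations), sc)   # idempotent
  allneg <- data.frame(var_id = "B", score = 1)
  expect_identical(nrow(signScreen(allneg, cr$correlations)), 0L)
  expect_error(signScreen(data.frame(var_id = "Z"), cr$correlations), "Z")
})

test_that("permutation importance and SHAP agree on a single dominant feature", {
  agree <- logical(12)
  for (s in seq_len(12)) {
    set.seed(400 + s)
    n <- 30; p <- 8
    X <- matrix(runif(n * p), n, p); colnames(X) <- sprintf("Var%02d", 1:p)
    y <- 5 * X[, 3]                      # noise-free dominant feature
    rf <- trainModel(mlConfig("random_forest", nTrees = 50), X, y, seed = s)
    top_pi <- permutationImportance(rf, X, y, nPerm = 30, seed = s)$var_id[1]
    top_sh <- names(which.max(shapleyScores(rf, X)$score))
    agree[s] <- top_pi == "Var03" && top_sh == "Var03"
  }
  expect_gte(mean(agree), 0.95)
})
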