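test_that("frequency voting counts appearances and applies strict/non-strict thresholds", {
  v <- voteFeatures(list(c("A", "B"), c("A", "C"), "A"), 50, strict = TRUE)
  expect_identical(v$var_id[v$selected], "A")
  expect_equal(v$pct[v$var_id == "A"], 100)
  expect_equal(v$pct[v$var_id == "B"], 100 / 3, tolerance = 1e-12)

  # published grid: 8 of 11 model lists -> 72.73%; 3 of 5 lists -> 60%
  lists11 <- c(lapply(1:8, function(i) "X258.244"), lapply(1:3, function(i) "other"))
  v11 <- voteFeatures(lists11, 50, strict = TRUE)
  expect_equal(round(v11$pct[v11$var_id == "X258.244"], 2), 72.73)
  expect_true(v11$selected[v11$var_id == "X258.244"])
  lists5 <- c(lapply(1:3, function(i) "X593.276"), lapply(1:2, function(i) "other"))
  v5 <- voteFeatures(lists5, 50, strict = FALSE)
  expect_equal(v5$pct[v5$var_id == "X593.276"], 60)
  expect_true(v5$selected[v5$var_id == "X593.276"])
  # at exactly 50%: strict rejects, non-strict accepts
  lists2 <- list("F", "other")
  expect_false(voteFeatures(lists2, 50, TRUE)$selected[1])
  expect_true(all(voteFeatures(lists2, 50, FALSE)$selected))
  expect_error(voteFeatures(list()), "no lists")
})

test_that("branch intersection is the sorted set intersection", {
  expect_identical(intersectBranches(c("b", "a", "c"), c("c", "b", "z")),
                   c("b", "c"))
  expect_identical(intersectBranches("a", "b"), character(0))
  expect_identical(intersectBranches(c("a", "b"), c("b", "a")), c("a", "b"))
  # order-independence
  expect_identical(intersectBranches(c("x", "y"), c("y", "x")),
                   intersectBranches(c("y", "x"), c("x", "y")))
})

test_that("m/z merging collapses equal masses and respects ppm tolerance", {
  mz <- c(F1 = 100.5, F2 = 200.25, F3 = 100.5)
  m <- mergeByMz(c("F1", "F2", "F3"), mz)
  expect_identical(nrow(m), 2L)
  expect_identical(m$members[m$mz == 100.5], "F1,F3")
  # all-distinct: compounds == features
  m2 <- mergeByMz(c("F1", "F2"), c(F1 = 1.111, F2 = 2.222))
  expect_identical(nrow(m2), 2L)
  # ppm chaining: 0.3 ppm apart merges at 10 ppm
  mz3 <- c(A = 328.1550, B = 328.1551)
  expect_identical(nrow(mergeByMz(c("A", "B"), mz3, "ppm", ppmTol = 10)), 1L)
  expect_identical(nrow(mergeByMz(c("A", "B"), c(A = 328.155, B = 328.655),
                                  "ppm", ppmTol = 10)), 2L)
  # input order does not matter
  expect_identical(mergeByMz(c("F3", "F1", "F2"), mz), m)
})

test_that("correlation matrix matches the double-loop oracle and flags degeneracy", {
  set.seed(61)
  X <- matrix(rnorm(40), 8, 5)
  colnames(X) <- paste0("f", 1:5)
  r <- correlationMatrix(X)
  expect_lt(max(abs(r - brute_cor_matrix(X))), 1e-12)
  expect_identical(unname(diag(r)), rep(1, 5))
  expect_identical(r, t(r))
  expect_equal(correlationMatrix(cbind(a = X[, 1], b = -X[, 1]))["a", "b"], -1)
  Xz <- cbind(X, z = rep(3, 8))
  expect_error(correlationMatrix(Xz), "z")
})

test_that("correlation grouping separates blocks and isolates independents", {
  blockCor <- function(sizes, r) {
    p <- sum(sizes)
    m <- diag(p)
    start <- cumsum(c(1, sizes))
    for (b in seq_along(sizes)) {
      ix <- start[b]:(start[b + 1] - 1)
      m[ix, ix] <- r
    }
    diag(m) <- 1
    rownames(m) <- colnames(m) <- paste0("f", 1:p)
    m
  }
  g <- groupFeatures(blockCor(c(3, 3), 0.95), cut = 0.5)
  expect_identical(length(unique(g)), 2L)
  gid <- groupFeatures(diag(4) + 0, cut = 0.5)
  expect_identical(length(unique(gid)), 4L)

  # synthetic three-block recovery; solvent slopes off so the block
  # factors are the only correlation source (the gradient otherwise ties
  # the all-active blocks together, which is a different, real effect)
  ok <- logical(10)
  cfg <- syntheticConfig(classSlope = 0, backgroundSlopeSd = 0)
  for (s in seq_len(10)) {
    sim <- simulateExtractStudy(cfg, seed = 70 + s)
    blk <- sim$truth$blockAssignment
    ids <- names(blk)[blk > 0]
    cm <- correlationMatrix(responses(sim$mset), ids)
    g <- groupFeatures(cm, cut = 0.5)
    # every planted block maps to a single recovered group, distinct per block
    lab <- vapply(1:3, function(b) {
      u <- unique(g[names(blk)[blk == b]])
      if (length(u) == 1) u else NA_integer_
    }, integer(1))
    ok[s] <- !anyNA(lab) && !anyDuplicated(lab)
  }
  expect_gte(mean(ok), 0.9)
})

test_that("activity cross-correlation has unit diagonal and monotone-inversion sign", {
  act <- data.frame(sample_id = 1:3, ic50_agi = c(1, 2, 4), ic50_dpph = c(9, 5, 2))
  act <- reciprocalTargets(act)
  r <- activityCrossCorrelation(act)
  expect_identical(dim(r), c(4L, 4L))
  expect_identical(unname(diag(r)), rep(1, 4))
  expect_lt(r["inv_agi", "ic50_agi"], 0)   # reciprocal reverses the order
  expect_identical(r, t(r))
  expect_error(activityCrossCorrelation(act[1:2, ]), "3 samples")
  actc <- act; actc$ic50_dpph <- 2; actc$inv_dpph <- 0.5
  expect_error(activityCrossCorrelation(actc), "constant")
})
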