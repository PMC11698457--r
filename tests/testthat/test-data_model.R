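test_that("feature-table CSV round trip preserves dimensions, order and values", {
  vals <- matrix(c(5, 0, 1.25, 3e4, 2, 7), nrow = 2, byrow = TRUE)
  path <- write_tiny_table(vals)
  mset <- readFeatureTable(path)
  expect_s4_class(mset, "MetaboSet")
  expect_identical(dim(responses(mset)), c(2L, 3L))
  expect_equal(unname(responses(mset)), vals)
  expect_identical(featureMeta(mset)$var_id, c("Var01", "Var02", "Var03"))
  # writer round trip: numeric payload stable
  out <- tempfile(fileext = ".csv")
  writeFeatureTable(mset, out)
  again <- readFeatureTable(out)
  expect_equal(responses(again), responses(mset))
  expect_equal(featureMeta(again)$mz, featureMeta(mset)$mz)
})

test_that("single-cell table and malformed tables hit the documented contracts", {
  path <- write_tiny_table(matrix(5.0, 1, 1))
  expect_equal(unname(responses(readFeatureTable(path))), matrix(5.0, 1, 1))

  # NaN cell names the sample and feature
  txt <- readLines(write_tiny_table(matrix(c(1, 2, NA, 4), 2)))
  bad <- tempfile(fileext = ".csv"); writeLines(txt, bad)
  expect_error(readFeatureTable(bad), "s1.*Var02")

  # negative response
  expect_error(readFeatureTable(write_tiny_table(matrix(c(1, -2), 1))),
               "negative response")

  # duplicate sample ids
  txt <- readLines(write_tiny_table(matrix(1:4, 2)))
  txt[3] <- sub("^s2", "s1", txt[3])
  dup <- tempfile(fileext = ".csv"); writeLines(txt, dup)
  expect_error(readFeatureTable(dup), "duplicate sample_id")
})

test_that("UV scaling centres, scales, drops constants, and inverts exactly", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 4, 4), c = c(2, 8, 5))
  expect_warning(sc <- uvScale(m), "zero-variance")
  expect_identical(sc@dropped, "b")
  expect_equal(unname(sc@values[, "a"]), c(-1, 0, 1))
  # invariants on every retained column
  expect_lt(max(abs(colMeans(sc@values))), 1e-10)
  expect_lt(max(abs(apply(sc@values, 2, sd) - 1)), 1e-10)
  expect_error(uvScale(m[1, , drop = FALSE]), "at least 2 samples")

  # algebraic round trip on random matrices
  set.seed(11)
  for (i in 1:5) {
    r <- matrix(rexp(60), 10, 6)
    sc <- uvScale(r)
    expect_lt(max(abs(unscale(sc) - r)), 1e-10)
  }
})

test_that("reciprocal targets are exact reciprocals and reverse the IC50 order", {
  act <- data.frame(sample_id = c("a", "b"), ic50_agi = c(4, 1),
                    ic50_dpph = c(2, 0.5))
  out <- reciprocalTargets(act)
  expect_equal(out$inv_agi, c(0.25, 1))
  expect_equal(out$inv_dpph, c(0.5, 2))
  expect_error(reciprocalTargets(transform(act, ic50_agi = c(0, 1))),
               "positive")
  set.seed(3)
  v <- rexp(25) + 0.01
  o <- reciprocalTargets(data.frame(sample_id = seq_along(v), ic50_agi = v,
                                    ic50_dpph = v))
  expect_identical(order(o$inv_agi), rev(order(v)))
})

test_that("class assignment flags exactly the 100% ethanol extracts", {
  expect_identical(as.character(assignClasses(c(100, 75, 0))),
                   c("active", "non_active", "non_active"))
  expect_true(all(assignClasses(rep(100, 4)) == "active"))
  expect_length(assignClasses(numeric(0)), 0)
  # idempotent and a function of ethanol only
  e <- c(0, 50, 100, 100, 25)
  expect_identical(assignClasses(e), assignClasses(e))
})

test_that("MetaboSet validity rejects inconsistent inputs", {
  sim <- simulateExtractStudy(seed = 1)
  expect_error(attachActivities(sim$mset,
    data.frame(sample_id = "nope", ic50_agi = 1, ic50_dpph = 1)),
    "missing samples")
  sm <- sampleMeta(sim$mset)[, c("sample_id", "ethanol_pct", "replicate")]
  fm <- featureMeta(sim$mset)
  resp <- responses(sim$mset)
  resp[1, 1] <- -5
  expect_error(MetaboSet(resp, sm, fm), "nonnegative")
})
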