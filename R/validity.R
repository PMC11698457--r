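# The three-criterion model-validity gate: R2Y-Q2 difference,
# response-permutation intercepts, and CV-ANOVA.

#' Validity thresholds
#'
#' The gate passes a model only if R2Y - Q2 <= `maxDiff`, the permuted-R2Y
#' regression intercept <= `maxR2Intercept`, the permuted-Q2 intercept <=
#' `maxQ2Intercept`, and every per-target CV-ANOVA p-value <= `maxP`.
#'
#' @param maxDiff,maxR2Intercept,maxQ2Intercept,maxP the four thresholds.
#' @return named list.
#' @export
validityThresholds <- function(maxDiff = 0.3, maxR2Intercept = 0.4,
                               maxQ2Intercept = 0.05, maxP = 0.05) {
  list(maxDiff = maxDiff, maxR2Intercept = maxR2Intercept,
       maxQ2Intercept = maxQ2Intercept, maxP = maxP)
}

#' Response-permutation test of a projection model
#'
#' Rows of the response block are shuffled (X untouched; multi-target
#' responses are permuted as whole rows so the targets stay paired), the
#' model is refitted at the original component configuration, and R2Y/Q2
#' are recorded against the absolute correlation of the permuted response
#' to the original. Two least-squares lines through the permuted points
#' plus the unpermuted point (at correlation 1) give the R2 and Q2
#' intercepts at correlation 0; a sound model has permuted fits decaying
#' well below the original, i.e. small (Q2: negative) intercepts.
#'
#' @param X a [ScaledResponses-class] or scaled matrix.
#' @param y response as in [fitProjection()].
#' @param method projection method (supervised).
#' @param nComponents,nOrth component configuration of the model under
#'   test (fixed across permutations).
#' @param cv a [cvConfig()].
#' @param nPerm number of permutations (default 20).
#' @param seed RNG seed for the permutations.
#' @param includeOriginal include the unpermuted point in the regression
#'   (the plotting convention that anchors the upper-right corner).
#' @return list with `runs` (data.frame: `correlation`, `r2y`, `q2`; the
#'   original point last), `r2Intercept`, `q2Intercept`.
#' @export
permutationTest <- function(X, y, method, nComponents, nOrth = 0,
                            cv = cvConfig(), nPerm = 20, seed = 1,
                            includeOriginal = TRUE) {
  if (nPerm < 2) stop("nPerm must be >= 2")
  method <- match.arg(method, c("PLS", "OPLS", "PLS-DA", "OPLS-DA"))
  Xs <- .as_x_matrix(X)
  da <- grepl("-DA$", method)
  if (da && is.factor(y)) {
    lv <- levels(droplevels(y))
    Yraw <- vapply(lv, function(l) as.numeric(y == l), numeric(length(y)))
  } else Yraw <- as.matrix(y)
  n <- nrow(Yraw)
  fitStats <- function(Yp) {
    Ys <- .scale_y(Yp)$values
    f <- .fit_raw(Xs, Ys, method, as.integer(nComponents), as.integer(nOrth))
    c(r2y = f$r2y,
      q2 = .q2_cv(Xs, Ys, method, as.integer(nComponents),
                  as.integer(nOrth), cv)$q2)
  }
  orig <- fitStats(Yraw)
  set.seed(as.integer(seed))
  runs <- lapply(seq_len(nPerm), function(i) {
    Yp <- Yraw[sample(n), , drop = FALSE]
    st <- fitStats(Yp)
    corr <- mean(abs(diag(stats::cor(Yp, Yraw))))
    c(correlation = corr, st)
  })
  runs <- as.data.frame(do.call(rbind, runs))
  runs <- rbind(runs, data.frame(correlation = 1, r2y = orig[["r2y"]],
                                 q2 = orig[["q2"]]))
  pts <- if (includeOriginal) runs else runs[seq_len(nPerm), ]
  r2Int <- unname(stats::coef(stats::lm(r2y ~ correlation, pts))[1])
  q2Int <- unname(stats::coef(stats::lm(q2 ~ correlation, pts))[1])
  list(runs = runs, r2Intercept = r2Int, q2Intercept = q2Int)
}

#' CV-ANOVA significance of a projection model
#'
#' F-test of whether cross-validated prediction beats the response mean:
#' F = ((SS - PRESS)/A) / (PRESS/(n - 1 - A)) with SS the mean-centred
#' total sum of squares of the selected target, PRESS its cross-validated
#' predictive residual sum of squares, and A the total number of fitted
#' components (predictive + orthogonal). F is clamped at 0 when the model
#' does no better than the mean, giving p = 1.
#'
#' @inheritParams permutationTest
#' @param targetIndex which response column to test (multi-target models
#'   report one p-value per output).
#' @return upper-tail p-value in [0, 1].
#' @export
cvAnova <- function(X, y, method, nComponents, nOrth = 0, cv = cvConfig(),
                    targetIndex = 1) {
  method <- match.arg(method, c("PLS", "OPLS", "PLS-DA", "OPLS-DA"))
  Xs <- .as_x_matrix(X)
  da <- grepl("-DA$", method)
  if (da && is.factor(y)) {
    lv <- levels(droplevels(y))
    Yraw <- vapply(lv, function(l) as.numeric(y == l), numeric(length(y)))
  } else Yraw <- as.matrix(y)
  Ys <- .scale_y(Yraw)$values
  qq <- .q2_cv(Xs, Ys, method, as.integer(nComponents), as.integer(nOrth), cv)
  press <- qq$pressPerTarget[targetIndex]
  ss <- colSums(Ys^2)[targetIndex]
  if (!is.finite(press)) stop("non-finite cross-validated residuals")
  n <- nrow(Ys)
  A <- as.integer(nComponents) + as.integer(nOrth)
  dfResid <- n - 1 - A
  if (dfResid < 1) stop("too many components for CV-ANOVA degrees of freedom")
  Fstat <- max(0, ((ss - press) / A) / (press / dfResid))
  stats::pf(Fstat, A, dfResid, lower.tail = FALSE)
}

#' Gate the model suite through the validity criteria
#'
#' Fits every supervised configuration of [modelTable()] (PCA has no
#' response and is never gated), runs the permutation test and CV-ANOVA,
#' and flags the models passing all criteria of [validityThresholds()].
#'
#' @param mset a `MetaboSet` with activities attached.
#' @param models model table (default [modelTable()]); the PCA row is
#'   skipped.
#' @param cv a [cvConfig()].
#' @param nPerm permutations per model (default 20).
#' @param seed RNG seed (one stream; each model's permutations derive
#'   from it deterministically).
#' @param thresholds a [validityThresholds()] list.
#' @return data.frame with one row per supervised model: `model`,
#'   `method`, `nComponents`, `nOrth`, `r2y`, `q2`, `diff`,
#'   `r2Intercept`, `q2Intercept`, `cvAnovaP` (max over targets),
#'   `valid`; per-target p-values in the list column `cvAnovaPerTarget`.
#' @export
validityGate <- function(mset, models = modelTable(), cv = cvConfig(),
                         nPerm = 20, seed = 1,
                         thresholds = validityThresholds()) {
  Xs <- uvScale(mset)
  sup <- models[models$method != "PCA", , drop = FALSE]
  rows <- vector("list", nrow(sup))
  for (i in seq_len(nrow(sup))) {
    method <- sup$method[i]
    yNames <- sup$y[[i]]
    yArg <- if (sup$da[i]) assignClasses(mset) else
      .build_y(mset, method, yNames)
    fit <- fitProjection(Xs, yArg, method, cv = cv)
    A <- ncol(fit@scores)
    nOrth <- ncol(fit@orthoScores)
    pt <- permutationTest(Xs, yArg, method, A, nOrth, cv, nPerm,
                          seed = seed + i)
    nTarget <- if (sup$da[i]) 1L else length(yNames)
    pvals <- vapply(seq_len(nTarget), function(tix)
      cvAnova(Xs, yArg, method, A, nOrth, cv, targetIndex = tix), numeric(1))
    diff <- fit@r2y - fit@q2
    valid <- diff <= thresholds$maxDiff &&
      pt$r2Intercept <= thresholds$maxR2Intercept &&
      pt$q2Intercept <= thresholds$maxQ2Intercept &&
      max(pvals) <= thresholds$maxP
    rows[[i]] <- data.frame(model = sup$model[i], method = method,
      nComponents = A, nOrth = nOrth, r2y = fit@r2y, q2 = fit@q2,
      diff = diff, r2Intercept = pt$r2Intercept, q2Intercept = pt$q2Intercept,
      cvAnovaP = max(pvals), valid = valid)
    rows[[i]]$cvAnovaPerTarget <- I(list(pvals))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$model
  out
}

#' Apply the validity rule to precomputed criterion values
#'
#' @param diff R2Y - Q2.
#' @param r2Intercept,q2Intercept permutation regression intercepts.
#' @param pvals CV-ANOVA p-value(s).
#' @param thresholds a [validityThresholds()] list.
#' @return logical.
#' @export
isValidModel <- function(diff, r2Intercept, q2Intercept, pvals,
                         thresholds = validityThresholds()) {
  diff <= thresholds$maxDiff &&
    r2Intercept <= thresholds$maxR2Intercept &&
    q2Intercept <= thresholds$maxQ2Intercept &&
    max(pvals) <= thresholds$maxP
}

#' Permutation plot (response-permutation diagnostics)
#'
#' R2Y and Q2 of the permuted refits against the absolute correlation of
#' the permuted response to the original, with the regression lines whose
#' intercepts the validity gate checks.
#'
#' @param pt result of [permutationTest()]
#' @param main plot title
#' @export
plotPermutation <- function(pt, main = "Response permutation") {
  runs <- pt$runs
  graphics::plot(runs$correlation, runs$r2y, pch = 19, col = "forestgreen",
                 xlim = c(0, 1), ylim = range(c(runs$r2y, runs$q2, 0, 1)),
                 xlab = "|correlation to original Y|", ylab = expression(R^2 ~ "/" ~ Q^2),
                 main = main)
  graphics::points(runs$correlation, runs$q2, pch = 17, col = "steelblue")
  graphics::abline(stats::lm(r2y ~ correlation, runs), col = "forestgreen", lty = 2)
  graphics::abline(stats::lm(q2 ~ correlation, runs), col = "steelblue", lty = 2)
  graphics::legend("bottomright", c(expression(R^2), expression(Q^2)),
                   pch = c(19, 17), col = c("forestgreen", "steelblue"), bty = "n")
}
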