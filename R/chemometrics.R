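# Branch A: the projection-model suite, cross-validated fit statistics,
# VIP, and loading-direction feature selection.

#' Cross-validation configuration
#'
#' @param nFolds number of folds (default 7, the usual chemometrics
#'   default).
#' @param assignment `"interleaved"` (sample i goes to fold i mod k;
#'   deterministic) or `"seeded_random"`.
#' @param seed seed used when `assignment = "seeded_random"`.
#' @return list of class `mzcCVConfig`.
#' @export
cvConfig <- function(nFolds = 7, assignment = c("interleaved", "seeded_random"),
                     seed = NULL) {
  out <- list(nFolds = as.integer(nFolds), assignment = match.arg(assignment),
              seed = seed)
  class(out) <- "mzcCVConfig"
  out
}

#' The 25-model projection suite
#'
#' One row per model configuration M1--M25: the projection method crossed
#' with the activity targets (1/IC50 and IC50 of the AGI and DPPH assays,
#' singly and in pairs). Discriminant rows (`*-DA`) are fitted on the
#' active/non-active class split; their listed continuous target is kept
#' as orientation metadata for feature selection.
#'
#' @return data.frame with columns `model`, `method`, `y` (list column of
#'   target names; empty for PCA), `da` (logical).
#' @export
modelTable <- function() {
  spec <- list(
    M1  = list("PCA", character(0)),
    M2  = list("PLS", "inv_agi"),
    M3  = list("PLS", "ic50_agi"),
    M4  = list("PLS-DA", "inv_agi"),
    M5  = list("OPLS-DA", "inv_agi"),
    M6  = list("OPLS", "inv_agi"),
    M7  = list("PLS", c("inv_agi", "inv_dpph")),
    M8  = list("OPLS", c("inv_agi", "inv_dpph")),
    M9  = list("PLS-DA", "ic50_agi"),
    M10 = list("OPLS-DA", "ic50_agi"),
    M11 = list("OPLS", "ic50_agi"),
    M12 = list("PLS", c("ic50_agi", "ic50_dpph")),
    M13 = list("OPLS", c("ic50_agi", "ic50_dpph")),
    M14 = list("PLS-DA", c("inv_agi", "inv_dpph")),
    M15 = list("OPLS-DA", c("inv_agi", "inv_dpph")),
    M16 = list("PLS-DA", c("ic50_agi", "ic50_dpph")),
    M17 = list("OPLS-DA", c("ic50_agi", "ic50_dpph")),
    M18 = list("PLS", "inv_dpph"),
    M19 = list("PLS-DA", "inv_dpph"),
    M20 = list("OPLS", "inv_dpph"),
    M21 = list("OPLS-DA", "inv_dpph"),
    M22 = list("PLS", "ic50_dpph"),
    M23 = list("PLS-DA", "ic50_dpph"),
    M24 = list("OPLS", "ic50_dpph"),
    M25 = list("OPLS-DA", "ic50_dpph"))
  df <- data.frame(model = names(spec),
                   method = vapply(spec, function(s) s[[1]], ""))
  df$y <- I(unname(lapply(spec, function(s) s[[2]])))
  df$da <- grepl("-DA$", df$method)
  rownames(df) <- df$model
  df
}

# Build the (raw) response block for a model row: continuous targets from
# the activity table, or UV-scalable class indicators for DA rows.
.build_y <- function(mset, method, yNames) {
  if (method == "PCA") return(NULL)
  if (grepl("-DA$", method)) {
    cls <- assignClasses(mset)
    Y <- cbind(active = as.numeric(cls == "active"),
               non_active = as.numeric(cls == "non_active"))
    if (length(unique(cls)) < 2) stop("discriminant model needs both classes")
    return(Y)
  }
  act <- activities(mset)
  missing <- setdiff(yNames, colnames(act))
  if (length(missing)) stop("unknown target(s): ", paste(missing, collapse = ", "))
  as.matrix(act[, yNames, drop = FALSE])
}

# UV-scale Y columns (population of the fit; n-1 sd).
.scale_y <- function(Y) {
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, stats::sd)
  if (any(sdv == 0)) stop("constant response column cannot be UV-scaled")
  list(values = sweep(sweep(Y, 2, mu), 2, sdv, "/"), center = mu, scale = sdv)
}

.as_x_matrix <- function(X) {
  if (methods::is(X, "ScaledResponses")) X@values
  else as.matrix(X)
}

#' Fit a latent-projection model
#'
#' NIPALS PCA/PLS with deflation; OPLS removes Y-orthogonal components
#' from X first (Y-predictive + orthogonal split) and fits the predictive
#' part on the filtered matrix. Initialization is deterministic and weight
#' signs are fixed, so refits are reproducible. When `nComponents` (and,
#' for OPLS, `nOrth`) is `NULL` it is chosen by the standard rule: add a
#' component while cross-validated Q2 improves by more than 0.01, capped
#' at 5 predictive (+5 orthogonal).
#'
#' @param X a [ScaledResponses-class] (or an already-scaled matrix).
#' @param y response: numeric vector/matrix of raw activity targets
#'   (UV-scaled internally), or a factor of class labels for `*-DA`
#'   methods (encoded as one UV-scaled indicator column per class).
#'   `NULL` for PCA.
#' @param method one of `"PCA"`, `"PLS"`, `"OPLS"`, `"PLS-DA"`,
#'   `"OPLS-DA"`.
#' @param nComponents number of predictive components, or `NULL` to
#'   auto-select.
#' @param nOrth number of orthogonal components (OPLS only), or `NULL`.
#' @param cv a [cvConfig()] used for Q2 and auto-selection.
#' @return a [LatentModel-class].
#' @examples
#' sim <- simulateExtractStudy(seed = 1)
#' Xs <- uvScale(sim$mset)
#' m <- fitProjection(Xs, activities(sim$mset)$inv_agi, "PLS")
#' m
#' @export
fitProjection <- function(X, y = NULL,
                          method = c("PLS", "PCA", "OPLS", "PLS-DA", "OPLS-DA"),
                          nComponents = NULL, nOrth = NULL, cv = cvConfig()) {
  method <- match.arg(method)
  Xs <- .as_x_matrix(X)
  if (any(!is.finite(Xs))) stop("X must be finite")
  featNames <- if (!is.null(colnames(Xs))) colnames(Xs) else
    sprintf("V%d", seq_len(ncol(Xs)))
  sampNames <- if (!is.null(rownames(Xs))) rownames(Xs) else
    sprintf("s%d", seq_len(nrow(Xs)))
  rank <- qr(Xs)$rank
  if (cv$nFolds > nrow(Xs)) cv$nFolds <- nrow(Xs)  # tiny-n: leave-one-out

  if (method == "PCA") {
    if (!is.null(y)) stop("PCA takes no response")
    A <- if (is.null(nComponents)) min(2L, rank) else as.integer(nComponents)
    if (A > rank)
      stop(sprintf("nComponents = %d exceeds the achievable rank %d", A, rank))
    f <- .fit_raw(Xs, NULL, "PCA", A, 0L)
    return(methods::new(Class = "LatentModel", method = method, yNames = character(0),
      W = f$W, P = f$P, C = f$C, scores = f$scores, Wo = f$Wo, Po = f$Po,
      orthoScores = f$To, r2x = f$r2x, r2y = numeric(0), q2 = numeric(0),
      r2yPerTarget = numeric(0), q2PerTarget = numeric(0), ssy = f$ssy,
      featureNames = featNames, sampleNames = sampNames,
      yCenter = numeric(0), yScale = numeric(0)))
  }

  if (is.null(y)) stop(method, " needs a response")
  da <- grepl("-DA$", method)
  if (da && is.factor(y)) {
    lv <- levels(droplevels(y))
    Yraw <- vapply(lv, function(l) as.numeric(y == l), numeric(length(y)))
    colnames(Yraw) <- lv
  } else {
    Yraw <- as.matrix(y)
    if (is.null(colnames(Yraw)))
      colnames(Yraw) <- paste0("y", seq_len(ncol(Yraw)))
  }
  ys <- .scale_y(Yraw)
  Ys <- ys$values
  yRank <- qr(Ys)$rank
  orth <- method %in% c("OPLS", "OPLS-DA")

  if (orth) {
    nPred <- if (is.null(nComponents)) min(yRank, rank) else as.integer(nComponents)
    if (nPred > rank)
      stop(sprintf("nComponents = %d exceeds the achievable rank %d", nPred, rank))
    if (is.null(nOrth)) {
      best <- .q2_cv(Xs, Ys, method, nPred, 0L, cv)
      nOrth <- 0L
      while (nOrth < 5L && nPred + nOrth + 1L <= rank) {
        cand <- .q2_cv(Xs, Ys, method, nPred, nOrth + 1L, cv)
        if (cand$q2 - best$q2 <= 0.01) break
        best <- cand
        nOrth <- nOrth + 1L
      }
      qq <- best
    } else {
      nOrth <- as.integer(nOrth)
      if (nPred + nOrth > rank)
        stop(sprintf("nComponents + nOrth = %d exceeds the achievable rank %d",
                     nPred + nOrth, rank))
      qq <- .q2_cv(Xs, Ys, method, nPred, nOrth, cv)
    }
    A <- nPred
  } else {
    nOrth <- 0L
    if (is.null(nComponents)) {
      A <- 1L
      best <- .q2_cv(Xs, Ys, method, A, 0L, cv)
      while (A < 5L && A + 1L <= rank) {
        cand <- .q2_cv(Xs, Ys, method, A + 1L, 0L, cv)
        if (cand$q2 - best$q2 <= 0.01) break
        best <- cand
        A <- A + 1L
      }
      qq <- best
    } else {
      A <- as.integer(nComponents)
      if (A > rank)
        stop(sprintf("nComponents = %d exceeds the achievable rank %d", A, rank))
      qq <- .q2_cv(Xs, Ys, method, A, 0L, cv)
    }
  }

  f <- .fit_raw(Xs, Ys, method, A, nOrth)
  methods::new(Class = "LatentModel", method = method, yNames = colnames(Yraw),
    W = f$W, P = f$P, C = f$C, scores = f$scores, Wo = f$Wo, Po = f$Po,
    orthoScores = f$To, r2x = f$r2x, r2y = f$r2y, q2 = qq$q2,
    r2yPerTarget = f$r2yPerTarget, q2PerTarget = qq$q2PerTarget, ssy = f$ssy,
    featureNames = featNames, sampleNames = sampNames,
    yCenter = ys$center, yScale = ys$scale)
}

#' Cross-validated Q2 for a model configuration
#'
#' Q2 = 1 - PRESS/SS over held-out folds, cumulative over components;
#' SS is the (mean-centred) total response sum of squares.
#'
#' @inheritParams fitProjection
#' @return a single number (can be negative when prediction is worse than
#'   the response mean).
#' @export
q2CV <- function(X, y, method = c("PLS", "OPLS", "PLS-DA", "OPLS-DA"),
                 nComponents = 1, nOrth = 0, cv = cvConfig()) {
  method <- match.arg(method)
  Xs <- .as_x_matrix(X)
  da <- grepl("-DA$", method)
  if (da && is.factor(y)) {
    lv <- levels(droplevels(y))
    Yraw <- vapply(lv, function(l) as.numeric(y == l), numeric(length(y)))
  } else Yraw <- as.matrix(y)
  Ys <- .scale_y(Yraw)$values
  .q2_cv(Xs, Ys, method, as.integer(nComponents), as.integer(nOrth), cv)$q2
}

#' Predict responses from a fitted latent model
#'
#' New rows must be scaled exactly like the training matrix (same feature
#' set; use the training [uvScale()] centres/scales).
#'
#' @param model a supervised [LatentModel-class]
#' @param newX scaled matrix (samples x features)
#' @param rescale return predictions on the raw response scale (default)
#'   rather than the internal UV scale.
#' @return matrix of predictions, one column per response.
#' @export
predictY <- function(model, newX, rescale = TRUE) {
  if (model@method == "PCA") stop("PCA has no response to predict")
  Xn <- .as_x_matrix(newX)
  fit <- list(W = model@W, P = model@P, C = model@C,
              Wo = model@Wo, Po = model@Po)
  pred <- .predict_raw(fit, Xn)
  colnames(pred) <- model@yNames
  if (rescale)
    pred <- sweep(sweep(pred, 2, model@yScale, "*"), 2, model@yCenter, "+")
  pred
}

#' Variable importance for projection (VIP)
#'
#' VIP_j = sqrt(p * sum_a ssy_a w_{aj}^2 / sum_a ssy_a) over the
#' predictive components (weights are unit-norm), so mean(VIP^2) = 1 and
#' features above 1 carry more than an average share of the explained
#' response variance.
#'
#' @param model a supervised [LatentModel-class] (not PCA)
#' @return named numeric vector, one VIP per feature.
#' @export
vip <- function(model) {
  if (model@method == "PCA") stop("VIP is undefined for PCA (no response)")
  W <- model@W
  ssy <- model@ssy
  if (!length(ssy)) stop("model has no fitted components")
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  v <- sqrt(nrow(W) * as.numeric((wn^2 %*% ssy) / sum(ssy)))
  stats::setNames(v, model@featureNames)
}

#' Activity direction of each predictive component
#'
#' The sign of the Pearson correlation between each score column and the
#' activity target; used to orient the loading ranking (the model itself
#' is sign-indeterminate, the biology is not).
#'
#' @param model a fitted [LatentModel-class]
#' @param target numeric activity vector (length = samples)
#' @return vector of +1/-1 per predictive component.
#' @export
activityDirection <- function(model, target) {
  Tm <- model@scores
  if (!ncol(Tm)) stop("model has no score columns")
  if (stats::sd(target) == 0) stop("target has zero variance")
  vapply(seq_len(ncol(Tm)), function(a) {
    if (stats::sd(Tm[, a]) == 0) stop("zero-variance score column ", a)
    s <- sign(stats::cor(Tm[, a], target))
    if (s == 0) 1 else s
  }, numeric(1))
}

#' Select the top activity-aligned features of a model
#'
#' Features are ranked by their first-predictive-component loading,
#' oriented so that activity-increasing features come first (via
#' [activityDirection()]), filtered to VIP > `vipMin`, and the first `k`
#' are returned. Fewer than `k` come back when the VIP filter exhausts the
#' candidates. Ties in loading are broken by stable feature order.
#'
#' @param model a supervised [LatentModel-class]
#' @param target activity vector used to orient the component (use the
#'   1/IC50 scale so "aligned" means "activity-increasing").
#' @param k list length cap (default 25).
#' @param vipMin VIP threshold; kept features must exceed it (default 1).
#' @return character vector of `var_id`s, most activity-aligned first.
#' @export
selectTopFeatures <- function(model, target, k = 25, vipMin = 1.0) {
  s1 <- activityDirection(model, target)[1]
  load1 <- model@P[, 1]
  v <- vip(model)
  ord <- order(-s1 * load1)       # stable: ties keep file order
  ord <- ord[v[ord] > vipMin]
  ids <- model@featureNames[ord]
  utils::head(ids, k)
}
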