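# Branch B: regression-model suite over the feature table, bootstrap
# augmentation, performance evaluation, and the three importance analyses
# (permutation delta-RMSE, mean-|Shapley|, correlation ranking with sign
# screening). Tree models run on the package's compiled CART backend.

#' Machine-learning model configuration
#'
#' Defaults fix each method to the study's settings: the single decision
#' tree is binary with >= 2 samples per leaf, does not split nodes below 5
#' samples and stops at 95% node purity (interpreted for regression as the
#' node variance falling to 5% of the root variance); the random forest
#' uses 100 trees with splits allowed down to 2 samples; gradient boosting
#' uses 100 depth-3 trees at learning rate 0.05; AdaBoost uses 100 stumps
#' with the linear loss of AdaBoost.R2 at learning rate 0.01.
#'
#' @param method one of `"linear_regression"`, `"decision_tree"`,
#'   `"random_forest"`, `"gradient_boosting"`, `"ada_boost"`.
#' @param ... overrides of the per-method defaults (`nTrees`, `mtry`,
#'   `minSplit`, `minLeaf`, `maxDepth`, `purity`, `learningRate`).
#' @return list of class `mzcMLConfig`.
#' @export
mlConfig <- function(method = c("random_forest", "linear_regression",
                                "decision_tree", "gradient_boosting",
                                "ada_boost"), ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    linear_regression = list(),
    decision_tree = list(minLeaf = 2, minSplit = 5, purity = 0.95,
                         maxDepth = 0L),
    random_forest = list(nTrees = 100L, minSplit = 2, minLeaf = 1,
                         mtry = NA_integer_, maxDepth = 0L),
    gradient_boosting = list(nTrees = 100L, maxDepth = 3L, minSplit = 2,
                             minLeaf = 1, learningRate = 0.05),
    ada_boost = list(nTrees = 100L, maxDepth = 1L, learningRate = 0.01))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown option(s) for ", method, ": ",
                        paste(bad, collapse = ", "))
  out <- utils::modifyList(defaults, over)
  out$method <- method
  class(out) <- "mzcMLConfig"
  out
}

#' Train a regression model
#'
#' @param config an [mlConfig()]
#' @param X samples-by-features matrix (raw responses)
#' @param y numeric target (1/IC50 AGI in the study design)
#' @param seed RNG seed for the stochastic learners.
#' @return fitted model of class `mzcModel` (predict with
#'   [predictModel()]).
#' @export
trainModel <- function(config, X, y, seed = 1) {
  stopifnot(inherits(config, "mzcMLConfig"))
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  set.seed(as.integer(seed))
  fit <- switch(config$method,
    linear_regression = {
      qx <- cbind(1, X)
      f <- stats::lm.fit(qx, y)
      beta <- f$coefficients
      beta[is.na(beta)] <- 0   # rank-deficient p > n: pivoted LS solution
      list(beta = beta)
    },
    decision_tree = {
      trees <- .cpp_grow_trees(X, y, 1L, ncol(X), as.integer(config$minSplit),
                               as.integer(config$minLeaf),
                               as.integer(config$maxDepth),
                               1 - config$purity, FALSE)
      list(trees = trees, weights = 1)
    },
    random_forest = {
      # regression-forest convention: a third of the features per split
      mtry <- if (is.na(config$mtry)) max(1L, ncol(X) %/% 3L)
              else as.integer(config$mtry)
      trees <- .cpp_grow_trees(X, y, as.integer(config$nTrees), mtry,
                               as.integer(config$minSplit),
                               as.integer(config$minLeaf),
                               as.integer(config$maxDepth), 0, TRUE)
      list(trees = trees, weights = rep(1 / config$nTrees, config$nTrees))
    },
    gradient_boosting = {
      f0 <- mean(y)
      resid <- y - f0
      trees <- vector("list", config$nTrees)
      for (b in seq_len(config$nTrees)) {
        tr <- .cpp_grow_trees(X, resid, 1L, ncol(X),
                              as.integer(config$minSplit),
                              as.integer(config$minLeaf),
                              as.integer(config$maxDepth), 0, FALSE)
        trees[[b]] <- tr[[1]]
        resid <- resid - config$learningRate * .cpp_predict_forest(tr, X)
      }
      list(trees = trees, f0 = f0, lr = config$learningRate)
    },
    ada_boost = {
      # AdaBoost.R2 with linear loss; stumps fitted on weighted resamples.
      n <- length(y)
      w <- rep(1 / n, n)
      trees <- list(); alphas <- numeric(0)
      for (b in seq_len(config$nTrees)) {
        idx <- sample.int(n, n, replace = TRUE, prob = w)
        tr <- .cpp_grow_trees(X[idx, , drop = FALSE], y[idx], 1L, ncol(X),
                              2L, 1L, as.integer(config$maxDepth), 0, FALSE)
        pred <- .cpp_predict_forest(tr, X)
        err <- abs(pred - y)
        emax <- max(err)
        if (emax == 0) { trees <- c(trees, tr); alphas <- c(alphas, 1); break }
        loss <- err / emax               # linear loss
        lbar <- sum(w * loss)
        if (lbar >= 0.5) { if (!length(trees)) { trees <- tr; alphas <- 1 }; break }
        beta <- lbar / (1 - lbar)
        trees <- c(trees, tr)
        alphas <- c(alphas, config$learningRate * log(1 / beta))
        w <- w * beta^(config$learningRate * (1 - loss))
        w <- w / sum(w)
      }
      list(trees = trees, alphas = alphas)
    })
  structure(list(method = config$method, config = config, fit = fit,
                 featureNames = colnames(X), trainX = X, trainY = y),
            class = "mzcModel")
}

#' Predict from a trained model
#'
#' @param model an `mzcModel` from [trainModel()]
#' @param X samples-by-features matrix
#' @return numeric prediction vector.
#' @export
predictModel <- function(model, X) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  f <- model$fit
  switch(model$method,
    linear_regression = as.numeric(cbind(1, X) %*% f$beta),
    decision_tree = ,
    random_forest = as.numeric(.cpp_predict_forest(f$trees, X)),
    gradient_boosting = {
      preds <- .cpp_predict_trees(f$trees, X)
      as.numeric(f$f0 + preds %*% rep(f$lr, ncol(preds)))
    },
    ada_boost = {
      preds <- .cpp_predict_trees(f$trees, X)
      # weighted median over the stumps (AdaBoost.R2 combination)
      apply(preds, 1, function(pr) {
        o <- order(pr)
        cw <- cumsum(f$alphas[o])
        pr[o][which(cw >= 0.5 * sum(f$alphas))[1]]
      })
    })
}

#' Stratified bootstrap augmentation
#'
#' Draws `nOut` rows with replacement, keeping the stratum (solvent class)
#' proportions as closely as integer rounding allows: the study design
#' (5 strata x 6 replicates, nOut = 50) yields exactly 10 rows per
#' stratum. Provenance (the source sample id) is recorded per row.
#'
#' @param mset a `MetaboSet` with activities.
#' @param nOut number of augmented samples (default 50).
#' @param seed RNG seed.
#' @return a `MetaboSet` of `nOut` samples whose colData carries
#'   `source_id` provenance.
#' @export
bootstrapAugment <- function(mset, nOut = 50, seed = 1) {
  sm <- sampleMeta(mset)
  strata <- factor(sm$ethanol_pct)
  if (any(table(strata) == 0)) stop("empty stratum")
  set.seed(as.integer(seed))
  # largest-remainder allocation of nOut over strata
  prop <- as.numeric(table(strata)) / nrow(sm)
  raw <- prop * nOut
  alloc <- floor(raw)
  rem <- nOut - sum(alloc)
  if (rem > 0) {
    o <- order(raw - alloc, decreasing = TRUE)
    alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1
  }
  idx <- unlist(lapply(seq_along(levels(strata)), function(s) {
    pool <- which(strata == levels(strata)[s])
    pool[sample.int(length(pool), alloc[s], replace = TRUE)]
  }))
  resp <- responses(mset)[idx, , drop = FALSE]
  newSm <- sm[idx, c("sample_id", "ethanol_pct", "replicate")]
  newSm$source_id <- newSm$sample_id
  newSm$sample_id <- sprintf("B%03d_%s", seq_along(idx), newSm$source_id)
  act <- activities(mset)[idx, ]
  act$sample_id <- newSm$sample_id
  out <- MetaboSet(resp, newSm, featureMeta(mset),
                   activities = act[, c("sample_id", "ic50_agi", "ic50_dpph")])
  out
}

#' Train/test split indices
#'
#' @param n number of samples
#' @param trainFraction fraction assigned to training (default 0.5)
#' @param seed RNG seed
#' @return list with integer vectors `train` and `test`.
#' @export
splitData <- function(n, trainFraction = 0.5, seed = 1) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  set.seed(as.integer(seed))
  nTrain <- round(n * trainFraction)
  if (nTrain < 1 || nTrain >= n) stop("degenerate split")
  train <- sort(sample.int(n, nTrain))
  list(train = train, test = setdiff(seq_len(n), train))
}

.rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

.r2 <- function(obs, pred) {
  ss <- sum((obs - mean(obs))^2)
  if (ss == 0) stop("constant observed values; R2 undefined")
  1 - sum((obs - pred)^2) / ss
}

#' Fit a model on a random split and report RMSE / R2
#'
#' R2 is the coefficient of determination of predicted vs true (so a
#' constant prediction at the test mean scores exactly 0, and worse can
#' go negative).
#'
#' @param config an [mlConfig()]
#' @param X samples-by-features matrix
#' @param y numeric target
#' @param split list from [splitData()] (indices `train`, `test`)
#' @param seed seed passed to [trainModel()]
#' @return one-row data.frame: `method`, `rmseTrain`, `r2Train`,
#'   `rmseTest`, `r2Test`.
#' @export
fitAndEvaluate <- function(config, X, y, split, seed = 1) {
  if (!length(split$train) || !length(split$test)) stop("degenerate split")
  X <- as.matrix(X)
  m <- trainModel(config, X[split$train, , drop = FALSE], y[split$train], seed)
  prTr <- predictModel(m, X[split$train, , drop = FALSE])
  prTe <- predictModel(m, X[split$test, , drop = FALSE])
  data.frame(method = config$method,
             rmseTrain = .rmse(y[split$train], prTr),
             r2Train = .r2(y[split$train], prTr),
             rmseTest = .rmse(y[split$test], prTe),
             r2Test = .r2(y[split$test], prTe))
}

#' Compare the model suite on one split (with or without augmentation)
#'
#' @param mset a `MetaboSet` with activities
#' @param target target column (default `inv_agi`)
#' @param methods methods to compare
#' @param trainFraction,seed split parameters
#' @param augment bootstrap-augment to `augmentTo` samples before
#'   splitting/fitting. The default order splits first and augments only
#'   the training side, which avoids provenance leakage into the test
#'   set; `order = "augment_then_split"` mirrors a
#'   pool-then-split protocol (leakage-prone; a warning is issued).
#' @param augmentTo augmented sample count (default 50)
#' @param order `"split_then_augment"` or `"augment_then_split"`
#' @return data.frame, one row per method.
#' @export
compareModels <- function(mset, target = "inv_agi",
                          methods = c("linear_regression", "decision_tree",
                                      "random_forest", "gradient_boosting",
                                      "ada_boost"),
                          trainFraction = 0.5, seed = 1, augment = FALSE,
                          augmentTo = 50,
                          order = c("split_then_augment", "augment_then_split")) {
  order <- match.arg(order)
  X <- responses(mset)
  y <- activities(mset)[[target]]
  if (augment && order == "augment_then_split") {
    warning("augment_then_split lets bootstrap copies of one extract land in both train and test")
    aug <- bootstrapAugment(mset, augmentTo, seed = seed)
    X <- responses(aug)
    y <- activities(aug)[[target]]
    split <- splitData(nrow(X), trainFraction, seed = seed + 1)
  } else if (augment) {
    split0 <- splitData(nrow(X), trainFraction, seed = seed + 1)
    sub <- mset[, split0$train]
    aug <- bootstrapAugment(sub, augmentTo, seed = seed)
    X <- rbind(responses(aug), X[split0$test, , drop = FALSE])
    y <- c(activities(aug)[[target]], y[split0$test])
    split <- list(train = seq_len(nrow(responses(aug))),
                  test = nrow(responses(aug)) + seq_along(split0$test))
  } else {
    split <- splitData(nrow(X), trainFraction, seed = seed + 1)
  }
  do.call(rbind, lapply(seq_along(methods), function(i)
    fitAndEvaluate(mlConfig(methods[i]), X, y, split, seed = seed + 10 + i)))
}

#' Permutation feature importance (delta RMSE)
#'
#' Each feature column is shuffled `nPerm` times; the score is the mean
#' permuted RMSE minus the baseline RMSE on the same evaluation set. A
#' feature the model never consults scores exactly 0.
#'
#' @param model an `mzcModel`
#' @param X evaluation matrix (default: the data the paper's ambiguity
#'   leaves open; pass the full dataset)
#' @param y evaluation target
#' @param nPerm number of permutations (default 100)
#' @param seed RNG seed
#' @return data.frame `var_id`, `score` (mean delta RMSE), `sd`, sorted
#'   decreasing by score.
#' @export
permutationImportance <- function(model, X, y, nPerm = 100, seed = 1) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  set.seed(as.integer(seed))
  if (model$method %in% c("decision_tree", "random_forest")) {
    st <- .cpp_perm_importance(model$fit$trees, X, y, as.integer(nPerm))
  } else {
    base <- .rmse(y, predictModel(model, X))
    n <- nrow(X)
    st <- vapply(seq_len(ncol(X)), function(j) {
      if (length(unique(X[, j])) == 1L) return(c(0, 0)) # constants can't move
      d <- vapply(seq_len(nPerm), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(n), j]
        .rmse(y, predictModel(model, Xp)) - base
      }, numeric(1))
      c(mean(d), stats::sd(d))
    }, numeric(2))
  }
  out <- data.frame(var_id = colnames(X), score = st[1, ], sd = st[2, ])
  out[order(-out$score, out$var_id), ]
}

#' Shapley feature attributions for tree models
#'
#' Exact interventional Shapley values for the package's tree ensembles:
#' each explicand is paired with every background row, the tree is walked
#' once per pair enumerating the divergent-feature paths, and the leaf
#' values are combined with the exact coalition weights. Local accuracy
#' holds to machine precision: per sample, the attributions sum to the
#' prediction minus the mean background prediction. The reported SHAP
#' score per feature is the mean absolute attribution over samples.
#'
#' @param model an `mzcModel` of a tree method (`decision_tree`,
#'   `random_forest`)
#' @param X explicand matrix (samples x features)
#' @param background background matrix (default: the model's training
#'   data)
#' @return list with `phi` (samples x features attribution matrix),
#'   `score` (per-feature mean |phi|, named), `base` (mean background
#'   prediction).
#' @export
shapleyScores <- function(model, X, background = NULL) {
  if (!model$method %in% c("decision_tree", "random_forest"))
    stop("Shapley attribution is implemented for tree models; got ",
         model$method)
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (is.null(background)) background <- model$trainX
  background <- as.matrix(background); storage.mode(background) <- "double"
  phi <- .cpp_shap_trees(model$fit$trees, X, background)
  colnames(phi) <- colnames(X)
  list(phi = phi,
       score = stats::setNames(colMeans(abs(phi)), colnames(X)),
       base = mean(.cpp_predict_forest(model$fit$trees, background)))
}

#' Correlation ranking of features against an activity target
#'
#' @param X samples-by-features matrix of raw responses
#' @param target activity vector (1/IC50 scale)
#' @param k list length (default 25)
#' @return list with `entries` (data.frame `var_id`, `score`; top-k most
#'   positive correlations first) and `correlations` (full named vector).
#' @export
correlationRanking <- function(X, target, k = 25) {
  X <- as.matrix(X)
  if (stats::sd(target) == 0) stop("constant target; correlations undefined")
  r <- apply(X, 2, function(col)
    if (stats::sd(col) == 0) NA_real_ else stats::cor(col, target))
  ord <- order(-r, na.last = TRUE)
  keep <- utils::head(ord[!is.na(r[ord])], k)
  list(entries = data.frame(var_id = colnames(X)[keep], score = r[keep],
                            row.names = NULL),
       correlations = stats::setNames(r, colnames(X)))
}

#' Remove negatively correlated features from an importance list
#'
#' Importance analyses flag influence in either direction; features whose
#' correlation to the activity target is <= 0 act as suppressors, not
#' actives, and are screened out (order otherwise preserved).
#'
#' @param entries data.frame with a `var_id` column (and any score)
#' @param correlations named correlation vector covering the listed
#'   features
#' @return the screened data.frame.
#' @export
signScreen <- function(entries, correlations) {
  miss <- setdiff(entries$var_id, names(correlations))
  if (length(miss)) stop("no correlation for: ", paste(miss, collapse = ", "))
  entries[correlations[entries$var_id] > 0, , drop = FALSE]
}

#' The five ML-branch importance lists
#'
#' Trains random forests on the plain and bootstrap-augmented data and
#' derives permutation-importance and SHAP top-`k` lists from each (4
#' lists), plus the correlation top-`k` (1 list). Every list is
#' sign-screened against the feature-to-target correlations before
#' voting.
#'
#' @param mset a `MetaboSet` with activities
#' @param target target column (default `inv_agi`)
#' @param k list length (default 25)
#' @param nPerm permutation-importance permutations (default 100)
#' @param augmentTo bootstrap sample count (default 50)
#' @param seed RNG seed
#' @return named list of five screened data.frames (`perm_rf`, `shap_rf`,
#'   `perm_rf_boot`, `shap_rf_boot`, `correlation`) plus attributes
#'   `correlations` (full vector).
#' @export
importanceSuite <- function(mset, target = "inv_agi", k = 25, nPerm = 100,
                            augmentTo = 50, seed = 1) {
  X <- responses(mset)
  y <- activities(mset)[[target]]
  aug <- bootstrapAugment(mset, augmentTo, seed = seed + 1)
  Xb <- responses(aug)
  yb <- activities(aug)[[target]]
  rf <- trainModel(mlConfig("random_forest"), X, y, seed = seed + 2)
  rfb <- trainModel(mlConfig("random_forest"), Xb, yb, seed = seed + 3)
  corRank <- correlationRanking(X, y, k)
  rvec <- corRank$correlations
  topk <- function(df) utils::head(df, k)
  lists <- list(
    perm_rf = topk(permutationImportance(rf, X, y, nPerm, seed = seed + 4)),
    shap_rf = {
      s <- shapleyScores(rf, X)
      data.frame(var_id = names(sort(s$score, decreasing = TRUE)),
                 score = as.numeric(sort(s$score, decreasing = TRUE)),
                 row.names = NULL)[seq_len(min(k, length(s$score))), ]
    },
    perm_rf_boot = topk(permutationImportance(rfb, Xb, yb, nPerm,
                                              seed = seed + 5)),
    shap_rf_boot = {
      s <- shapleyScores(rfb, Xb)
      data.frame(var_id = names(sort(s$score, decreasing = TRUE)),
                 score = as.numeric(sort(s$score, decreasing = TRUE)),
                 row.names = NULL)[seq_len(min(k, length(s$score))), ]
    },
    correlation = corRank$entries)
  lists <- lapply(lists, signScreen, correlations = rvec)
  attr(lists, "correlations") <- rvec
  lists
}
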