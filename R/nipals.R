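# NIPALS engines. All functions here work on matrices that are already
# centred/scaled; X is samples x features, Y samples x targets. Scores are
# deterministic: iteration starts from the largest-sum-of-squares column,
# and each weight vector is sign-fixed so its largest-magnitude entry is
# positive (NIPALS is sign-indeterminate otherwise).

.fix_sign <- function(w) {
  i <- which.max(abs(w))
  if (w[i] < 0) -w else w
}

.nipals_pca <- function(X, ncomp, tol = 1e-10, maxit = 500) {
  n <- nrow(X); p <- ncol(X)
  Tm <- matrix(0, n, 0); P <- matrix(0, p, 0); r2x <- numeric(0)
  ssx <- sum(X^2); Xr <- X
  for (a in seq_len(ncomp)) {
    t <- Xr[, which.max(colSums(Xr^2))]
    if (sum(t^2) < 1e-12 * max(ssx, 1)) break
    for (it in seq_len(maxit)) {
      p_ <- crossprod(Xr, t) / sum(t^2)
      p_ <- p_ / sqrt(sum(p_^2))
      tNew <- Xr %*% p_
      if (sum((tNew - t)^2) < tol^2 * sum(tNew^2)) { t <- tNew; break }
      t <- tNew
    }
    p_ <- .fix_sign(p_)
    t <- Xr %*% p_
    Xr <- Xr - tcrossprod(t, p_)
    Tm <- cbind(Tm, t); P <- cbind(P, p_)
    r2x <- c(r2x, sum(t^2) / ssx)
  }
  list(scores = Tm, P = P, r2x = r2x)
}

.nipals_pls <- function(X, Y, ncomp, tol = 1e-10, maxit = 500) {
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  W <- P <- matrix(0, p, 0); C <- matrix(0, m, 0); Tm <- matrix(0, n, 0)
  ssy_comp <- r2x <- numeric(0)
  ssx <- sum(X^2); ssy <- sum(Y^2)
  Xr <- X; Yr <- Y
  for (a in seq_len(ncomp)) {
    u <- Yr[, which.max(colSums(Yr^2))]
    if (sum(u^2) < 1e-12 * max(ssy, 1)) break
    t <- NULL
    for (it in seq_len(maxit)) {
      w <- crossprod(Xr, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tNew <- Xr %*% w
      cvec <- crossprod(Yr, tNew) / sum(tNew^2)
      u <- Yr %*% cvec / sum(cvec^2)
      if (!is.null(t) && sum((tNew - t)^2) < tol^2 * sum(tNew^2)) { t <- tNew; break }
      t <- tNew
    }
    if (is.null(t) || sum(t^2) < 1e-12) break
    w <- .fix_sign(w)
    t <- Xr %*% w
    cvec <- crossprod(Yr, t) / sum(t^2)
    p_ <- crossprod(Xr, t) / sum(t^2)
    Xr <- Xr - tcrossprod(t, p_)
    Yr <- Yr - tcrossprod(t, cvec)
    W <- cbind(W, w); P <- cbind(P, p_); C <- cbind(C, cvec); Tm <- cbind(Tm, t)
    ssy_comp <- c(ssy_comp, sum(t^2) * sum(cvec^2))
    r2x <- c(r2x, sum(t^2 %*% t(p_^2)) / ssx)
  }
  r2yPer <- if (ncol(Tm)) 1 - colSums(Yr^2) / colSums(Y^2) else rep(0, m)
  list(W = W, P = P, C = C, scores = Tm, ssy = ssy_comp, r2x = r2x,
       r2y = if (ssy > 0) 1 - sum(Yr^2) / ssy else 0,
       r2yPerTarget = r2yPer)
}

# Y-orthogonal filtering (OPLS). Returns the orthogonal blocks and the
# filtered X; the predictive part is a plain PLS fit on the filtered X.
.opls_filter <- function(X, Y, nPred, nOrth) {
  Y <- as.matrix(Y)
  p <- ncol(X)
  Wo <- Po <- matrix(0, p, 0); To <- matrix(0, nrow(X), 0)
  Xr <- X
  for (k in seq_len(nOrth)) {
    base <- .nipals_pls(Xr, Y, nPred)
    Wp <- base$W
    if (!ncol(Wp)) break
    t <- Xr %*% Wp[, 1]
    p_ <- crossprod(Xr, t) / sum(t^2)
    wo <- p_ - Wp %*% solve(crossprod(Wp), crossprod(Wp, p_))
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-8) break
    wo <- .fix_sign(wo / nwo)
    to <- Xr %*% wo
    po <- crossprod(Xr, to) / sum(to^2)
    Xr <- Xr - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  list(Wo = Wo, Po = Po, To = To, Xfiltered = Xr)
}

.fit_raw <- function(X, Y, method, nPred, nOrth) {
  if (method == "PCA") {
    f <- .nipals_pca(X, nPred)
    return(list(W = f$P, P = f$P, C = matrix(0, 0, ncol(f$P)),
                scores = f$scores, Wo = matrix(0, ncol(X), 0),
                Po = matrix(0, ncol(X), 0), To = matrix(0, nrow(X), 0),
                ssy = numeric(0), r2x = f$r2x, r2y = numeric(0),
                r2yPerTarget = numeric(0)))
  }
  orth <- if (method %in% c("OPLS", "OPLS-DA") && nOrth > 0)
    .opls_filter(X, Y, nPred, nOrth)
  else list(Wo = matrix(0, ncol(X), 0), Po = matrix(0, ncol(X), 0),
            To = matrix(0, nrow(X), 0), Xfiltered = X)
  f <- .nipals_pls(orth$Xfiltered, Y, nPred)
  c(f, orth[c("Wo", "Po", "To")])
}

# Predict (scaled-space) Y for new scaled X rows.
.predict_raw <- function(fit, Xnew) {
  Xn <- as.matrix(Xnew)
  if (ncol(fit$Wo)) {
    for (k in seq_len(ncol(fit$Wo))) {
      to <- Xn %*% fit$Wo[, k]
      Xn <- Xn - tcrossprod(to, fit$Po[, k])
    }
  }
  if (!ncol(fit$W)) return(matrix(0, nrow(Xn), max(1, nrow(fit$C))))
  Wstar <- fit$W %*% solve(crossprod(fit$P, fit$W))
  (Xn %*% Wstar) %*% t(fit$C)
}

# Fold assignment for cross-validation.
.cv_folds <- function(n, cv) {
  k <- cv$nFolds
  if (k < 2 || k > n) stop("nFolds must be in [2, n]")
  f <- ((seq_len(n) - 1L) %% k) + 1L
  if (cv$assignment == "seeded_random") {
    if (!is.null(cv$seed)) set.seed(cv$seed)
    f <- sample(f)
  }
  f
}

# Cross-validated PRESS -> Q2 (total and per target) at a fixed component
# configuration. X and Y are globally scaled; folds reuse that scaling.
.q2_cv <- function(X, Y, method, nPred, nOrth, cv) {
  Y <- as.matrix(Y)
  folds <- .cv_folds(nrow(X), cv)
  press <- rep(0, ncol(Y))
  for (k in sort(unique(folds))) {
    inTrain <- folds != k
    if (sum(!inTrain) < 1) stop("cross-validation fold with no held-out sample")
    fit <- .fit_raw(X[inTrain, , drop = FALSE], Y[inTrain, , drop = FALSE],
                    method, nPred, nOrth)
    pred <- .predict_raw(fit, X[!inTrain, , drop = FALSE])
    press <- press + colSums((Y[!inTrain, , drop = FALSE] - pred)^2)
  }
  ssy <- colSums(Y^2)
  list(q2 = 1 - sum(press) / sum(ssy), q2PerTarget = as.numeric(1 - press / ssy),
       press = sum(press), ssy = sum(ssy), pressPerTarget = press)
}
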