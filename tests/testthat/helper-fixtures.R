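# Shared fixtures and independent oracles for the suite.

# tiny feature-table CSV (var_id:mz header convention) written to a temp file
write_tiny_table <- function(values, path = tempfile(fileext = ".csv"),
                             mz = NULL) {
  n <- nrow(values); p <- ncol(values)
  if (is.null(mz)) mz <- round(100 + seq_len(p) * 1.111, 3)
  df <- data.frame(sample_id = sprintf("s%d", seq_len(n)),
                   ethanol_pct = rep_len(c(0, 25, 50, 75, 100), n),
                   replicate = seq_len(n))
  vals <- as.data.frame(values)
  names(vals) <- sprintf("Var%02d:%s", seq_len(p), mz)
  utils::write.csv(cbind(df, vals), path, row.names = FALSE, quote = FALSE)
  path
}

# brute-force pairwise Pearson matrix (double loop, no cor())
brute_cor_matrix <- function(X) {
  p <- ncol(X)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    xi <- X[, i] - mean(X[, i]); xj <- X[, j] - mean(X[, j])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# interventional coalition value v(S): mean over background rows of the
# model prediction with features in S taken from x, the rest from z
coalition_value <- function(model, x, S, background) {
  rows <- background
  for (j in S) rows[, j] <- x[j]
  mean(predictModel(model, rows))
}

# exact Shapley by full coalition enumeration (independent oracle, <= ~12
# features)
brute_shapley <- function(model, x, background) {
  p <- length(x)
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  key <- function(S) paste0("S", paste(sort(S), collapse = ","))
  vals <- vapply(subsets, function(S)
    coalition_value(model, x, S, background), numeric(1))
  names(vals) <- vapply(subsets, key, "")
  for (j in seq_len(p)) {
    for (i in seq_along(subsets)) {
      S <- subsets[[i]]
      if (j %in% S) next
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[j] <- phi[j] + w * (vals[[key(c(S, j))]] - vals[[key(S)]])
    }
  }
  phi
}

# a one-split regression stump as a trained model (via the real trainer on
# data that forces the split)
make_stump <- function(n = 8, p = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  colnames(X) <- sprintf("Var%02d", seq_len(p))
  y <- ifelse(X[, 1] > 0.5, 10, 0)
  trainModel(mlConfig("decision_tree", maxDepth = 1, minSplit = 2,
                      minLeaf = 1), X, y, seed = seed)
}
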