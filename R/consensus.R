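# Frequency voting within each branch, branch intersection, m/z-based
# merge of features into compounds, and the correlation post-analyses.

#' Frequency voting over feature lists
#'
#' Counts in how many of the source lists each feature appears and selects
#' those above the threshold. The chemometric branch votes strictly
#' (> 50% of the valid models), the ML branch non-strictly (>= 50% of its
#' five lists) -- exactly how each branch's rule is worded.
#'
#' @param lists list of character vectors (or data.frames with a `var_id`
#'   column)
#' @param thresholdPct percentage threshold (default 50)
#' @param strict if `TRUE`, selection requires strictly more than the
#'   threshold; otherwise at least the threshold.
#' @return data.frame `var_id`, `count`, `pct`, `selected`, ordered by
#'   decreasing percentage then `var_id`.
#' @export
voteFeatures <- function(lists, thresholdPct = 50, strict = TRUE) {
  if (!length(lists)) stop("no lists to vote over")
  ids <- lapply(lists, function(l) unique(if (is.data.frame(l)) l$var_id else l))
  tab <- table(unlist(ids))
  pct <- 100 * as.numeric(tab) / length(lists)
  out <- data.frame(var_id = names(tab), count = as.numeric(tab), pct = pct)
  out$selected <- if (strict) out$pct > thresholdPct else out$pct >= thresholdPct
  out[order(-out$pct, out$var_id), , drop = FALSE]
}

#' Intersect the two branch predictions
#'
#' @param statSelected,mlSelected character vectors of `var_id`s selected
#'   by the chemometric and ML branches
#' @return sorted character vector (deterministic order).
#' @export
intersectBranches <- function(statSelected, mlSelected) {
  sort(intersect(unique(statSelected), unique(mlSelected)))
}

#' Merge predicted features into compounds by m/z
#'
#' Features produced by the same compound share an m/z value; predictions
#' are collapsed by m/z equality at 3 decimal places (`"exact3dp"`, the
#' reported precision) or within a ppm tolerance (`"ppm"`,
#' single-linkage chaining on the sorted m/z values).
#'
#' @param varIds character vector of predicted features
#' @param mz named numeric vector (or data.frame `var_id`,`mz`) giving
#'   each feature's m/z
#' @param tolMode `"exact3dp"` or `"ppm"`
#' @param ppmTol tolerance in ppm for `"ppm"` mode (default 10)
#' @return data.frame with one row per compound: `mz`, `members`
#'   (comma-joined `var_id`s), `n_members`; ordered by m/z.
#' @export
mergeByMz <- function(varIds, mz, tolMode = c("exact3dp", "ppm"), ppmTol = 10) {
  tolMode <- match.arg(tolMode)
  if (is.data.frame(mz)) mz <- stats::setNames(mz$mz, mz$var_id)
  varIds <- unique(varIds)
  miss <- setdiff(varIds, names(mz))
  if (length(miss)) stop("no m/z for: ", paste(miss, collapse = ", "))
  v <- mz[varIds]
  if (tolMode == "exact3dp") {
    grp <- as.integer(factor(sprintf("%.3f", v)))
  } else {
    o <- order(v)
    g <- integer(length(v)); gid <- 1L; g[o[1]] <- 1L
    for (i in seq_along(o)[-1]) {
      gap <- (v[o[i]] - v[o[i - 1]]) / v[o[i - 1]] * 1e6
      if (gap > ppmTol) gid <- gid + 1L
      g[o[i]] <- gid
    }
    grp <- g
  }
  agg <- lapply(split(seq_along(varIds), grp), function(ix)
    data.frame(mz = mean(v[ix]),
               members = paste(sort(varIds[ix]), collapse = ","),
               n_members = length(ix)))
  out <- do.call(rbind, agg)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix over a feature subset
#'
#' @param X samples-by-features raw response matrix
#' @param featureSubset columns to include (default all)
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(X, featureSubset = colnames(X)) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  sub <- X[, featureSubset, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(sub)[sds == 0], collapse = ", "))
  r <- stats::cor(sub)
  diag(r) <- 1
  r
}

#' Group features by correlation structure
#'
#' Average-linkage hierarchical clustering on the distance 1 - r, cut at
#' the configured height. A reproducible stand-in for the by-eye grouping
#' of a correlation heatmap.
#'
#' @param corrMat correlation matrix from [correlationMatrix()]
#' @param cut cut height on 1 - r (default 0.5)
#' @return named integer vector of group memberships.
#' @export
groupFeatures <- function(corrMat, cut = 0.5) {
  d <- stats::as.dist(1 - corrMat)
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, h = cut)
}

#' Cross-correlations of the four activity readouts
#'
#' The 4x4 Pearson matrix over 1/IC50 AGI, IC50 AGI, 1/IC50 DPPH and
#' IC50 DPPH; the off-diagonal AGI-vs-DPPH entries measure how far
#' glucosidase inhibition tracks antioxidant capacity across extracts.
#'
#' @param activity data.frame with the four activity columns (see
#'   [reciprocalTargets()])
#' @return 4x4 symmetric correlation matrix, unit diagonal.
#' @export
activityCrossCorrelation <- function(activity) {
  cols <- c("inv_agi", "ic50_agi", "inv_dpph", "ic50_dpph")
  if (!all(cols %in% colnames(activity)))
    stop("activity table must have columns: ", paste(cols, collapse = ", "))
  if (nrow(activity) < 3) stop("need at least 3 samples")
  m <- as.matrix(activity[, cols])
  if (any(apply(m, 2, stats::sd) == 0)) stop("constant activity column")
  r <- stats::cor(m)
  diag(r) <- 1
  r
}

#' Correlation heatmap of predicted features
#'
#' @param corrMat matrix from [correlationMatrix()]
#' @param ... passed to [pheatmap::pheatmap()] when available; falls back
#'   to a base-graphics image otherwise.
#' @export
plotCorrelationHeatmap <- function(corrMat, ...) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(corrMat, ...)
  } else {
    n <- ncol(corrMat)
    graphics::image(seq_len(n), seq_len(n), corrMat[, n:1], zlim = c(-1, 1),
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                    axes = FALSE, xlab = "", ylab = "")
    graphics::axis(1, seq_len(n), colnames(corrMat), las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(n), rev(colnames(corrMat)), las = 2, cex.axis = 0.6)
  }
  invisible(corrMat)
}
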