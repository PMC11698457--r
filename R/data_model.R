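# File I/O, UV scaling, reciprocal transform and class assignment.

#' Read a feature table CSV into a MetaboSet
#'
#' Expected layout: header row; columns `sample_id`, `ethanol_pct`,
#' `replicate`, then one column per m/z feature. Feature columns are named
#' either plain (`Var01`, matched against the companion metadata CSV given
#' as `featureMetaPath` with columns `var_id,mz`) or by the `var_id:mz`
#' convention (`Var01:123.456`), in which case no companion file is needed.
#' Row and column order are preserved; nothing is re-sorted.
#'
#' @param path CSV file path.
#' @param featureMetaPath optional companion CSV with columns `var_id,mz`.
#' @return a `MetaboSet` (without activities; see [readActivityTable()]).
#' @export
readFeatureTable <- function(path, featureMetaPath = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "ethanol_pct", "replicate")
  if (!all(need %in% colnames(df)))
    stop("feature table must start with columns sample_id, ethanol_pct, replicate")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  featCols <- setdiff(colnames(df), need)
  if (!length(featCols)) stop("no feature columns found")
  resp <- as.matrix(df[, featCols, drop = FALSE])
  storage.mode(resp) <- "double"
  bad <- which(!is.finite(resp), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("missing/non-finite response at sample '%s', feature '%s'",
                 df$sample_id[bad[1, 1]], featCols[bad[1, 2]]))
  neg <- which(resp < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative response at sample '%s', feature '%s'",
                 df$sample_id[neg[1, 1]], featCols[neg[1, 2]]))
  if (all(grepl(":", featCols, fixed = TRUE))) {
    parts <- strsplit(featCols, ":", fixed = TRUE)
    fmeta <- data.frame(var_id = vapply(parts, `[`, "", 1L),
                        mz = as.numeric(vapply(parts, `[`, "", 2L)))
  } else if (!is.null(featureMetaPath)) {
    fmeta <- utils::read.csv(featureMetaPath, stringsAsFactors = FALSE)
    if (!all(c("var_id", "mz") %in% colnames(fmeta)))
      stop("feature metadata CSV must have columns var_id, mz")
    fmeta <- fmeta[match(featCols, fmeta$var_id), c("var_id", "mz")]
    if (anyNA(fmeta$var_id))
      stop("feature metadata is missing entries for: ",
           paste(featCols[is.na(fmeta$var_id)], collapse = ", "))
  } else {
    stop("feature columns are not in 'var_id:mz' form and no featureMetaPath given")
  }
  colnames(resp) <- fmeta$var_id
  MetaboSet(resp, df[, need], fmeta)
}

#' Write a feature table CSV (inverse of readFeatureTable)
#'
#' Numeric payload is written in full precision with the `var_id:mz`
#' header convention, so that a read/write round trip is value-stable.
#'
#' @param mset a `MetaboSet`
#' @param path output CSV path
#' @export
writeFeatureTable <- function(mset, path) {
  fm <- featureMeta(mset)
  sm <- sampleMeta(mset)[, c("sample_id", "ethanol_pct", "replicate")]
  resp <- responses(mset)
  colnames(resp) <- paste0(fm$var_id, ":", fm$mz)
  utils::write.csv(cbind(sm, as.data.frame(resp, check.names = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity table CSV
#'
#' Columns `sample_id,ic50_agi,ic50_dpph` (IC50 in ppm). Reciprocals
#' `inv_agi`, `inv_dpph` are computed on read (stronger activity, larger
#' value).
#'
#' @param path CSV file path
#' @return data.frame with the five activity columns.
#' @export
readActivityTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "ic50_agi", "ic50_dpph") %in% colnames(df)))
    stop("activity table must have columns sample_id, ic50_agi, ic50_dpph")
  reciprocalTargets(df)
}

#' Populate reciprocal activity targets
#'
#' IC50 decreases as the extract gets more potent; the regression targets
#' are the reciprocals 1/IC50 so that larger means more active.
#'
#' @param activity data.frame with positive `ic50_agi` and `ic50_dpph`.
#' @return the same data.frame with `inv_agi` and `inv_dpph` (re)computed.
#' @export
reciprocalTargets <- function(activity) {
  for (nm in c("ic50_agi", "ic50_dpph")) {
    v <- activity[[nm]]
    if (is.null(v)) stop("missing column ", nm)
    if (any(!is.finite(v)) || any(v <= 0)) stop(nm, " must be positive and finite")
  }
  activity$inv_agi <- 1 / activity$ic50_agi
  activity$inv_dpph <- 1 / activity$ic50_dpph
  activity
}

#' Attach activities to a MetaboSet
#'
#' @param mset a `MetaboSet`
#' @param activity data.frame with `sample_id`, `ic50_agi`, `ic50_dpph`
#' @return the `MetaboSet` with activity columns merged into its colData.
#' @export
attachActivities <- function(mset, activity) {
  activity <- reciprocalTargets(activity)
  idx <- match(sampleMeta(mset)$sample_id, activity$sample_id)
  if (anyNA(idx))
    stop("activity table is missing samples: ",
         paste(sampleMeta(mset)$sample_id[is.na(idx)], collapse = ", "))
  for (nm in c("ic50_agi", "ic50_dpph", "inv_agi", "inv_dpph"))
    SummarizedExperiment::colData(mset)[[nm]] <- activity[[nm]][idx]
  methods::validObject(mset)
  mset
}

#' Unit-variance (UV) scale a response matrix
#'
#' Each feature is centred to mean zero and divided by its sample standard
#' deviation (n-1 denominator). Zero-variance features cannot be scaled;
#' they are dropped with a warning and recorded in `@dropped`.
#'
#' @param x a `MetaboSet` or samples-by-features numeric matrix.
#' @return a [ScaledResponses-class] object.
#' @export
uvScale <- function(x) {
  m <- if (methods::is(x, "MetaboSet")) responses(x) else as.matrix(x)
  if (nrow(m) < 2) stop("UV scaling needs at least 2 samples")
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
  vals <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  methods::new("ScaledResponses", values = vals, center = mu[keep],
               scale = sdv[keep], dropped = colnames(m)[!keep])
}

#' Invert UV scaling
#'
#' @param sc a `ScaledResponses`
#' @return the raw matrix over the retained features.
#' @export
unscale <- function(sc) {
  sweep(sweep(sc@values, 2, sc@scale, "*"), 2, sc@center, "+")
}

#' Active / non-active class labels
#'
#' The discriminant models use the solvent design as class labels: the
#' 100% ethanol extracts are the `active` class (they show the strongest
#' AGI activity), everything else is `non_active`.
#'
#' @param x a `MetaboSet` or a numeric vector of ethanol percentages.
#' @return factor with levels `active`, `non_active` (one per sample).
#' @export
assignClasses <- function(x) {
  e <- if (methods::is(x, "MetaboSet")) sampleMeta(x)$ethanol_pct else x
  factor(ifelse(e == 100, "active", "non_active"),
         levels = c("active", "non_active"))
}
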