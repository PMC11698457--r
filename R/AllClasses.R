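#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd cor setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib mzConsensus, .registration = TRUE
NULL

#' MetaboSet: an LC-MS feature table with sample metadata and activities
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one assay `"response"` (features as rows, samples as columns; peak
#' responses, zero meaning not detected). `rowData` carries the feature
#' metadata (`var_id`, `mz`), `colData` the sample metadata (`sample_id`,
#' `ethanol_pct`, `replicate`) and, once attached, the bioassay activities
#' (`ic50_agi`, `ic50_dpph` and their reciprocals `inv_agi`, `inv_dpph`).
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("MetaboSet", contains = "SummarizedExperiment")

setValidity("MetaboSet", function(object) {
  msg <- character(0)
  if (!"response" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'response' is required")
  else {
    a <- SummarizedExperiment::assay(object, "response")
    if (anyNA(a)) msg <- c(msg, "responses must not contain missing values")
    else if (any(a < 0)) msg <- c(msg, "responses must be nonnegative")
  }
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("var_id", "mz") %in% colnames(rd)))
    msg <- c(msg, "rowData must have columns 'var_id' and 'mz'")
  else {
    if (anyDuplicated(rd$var_id)) msg <- c(msg, "duplicate var_id in feature metadata")
    if (any(!is.finite(rd$mz)) || any(rd$mz <= 0)) msg <- c(msg, "mz must be positive")
  }
  if (!all(c("sample_id", "ethanol_pct", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must have columns 'sample_id', 'ethanol_pct', 'replicate'")
  else {
    if (anyDuplicated(cd$sample_id)) msg <- c(msg, "duplicate sample_id")
    if (any(cd$ethanol_pct < 0 | cd$ethanol_pct > 100))
      msg <- c(msg, "ethanol_pct must lie in [0, 100]")
  }
  for (nm in c("ic50_agi", "ic50_dpph"))
    if (nm %in% colnames(cd) && any(cd[[nm]] <= 0))
      msg <- c(msg, paste0(nm, " must be positive"))
  if (length(msg)) msg else TRUE
})

#' Construct a MetaboSet
#'
#' @param responses numeric matrix, samples in rows and features in columns
#'   (the orientation of the CSV interchange format); transposed internally
#'   to the features-by-samples assay.
#' @param sampleData data.frame with columns `sample_id`, `ethanol_pct`,
#'   `replicate` (one row per sample).
#' @param featureData data.frame with columns `var_id`, `mz` (one row per
#'   feature).
#' @param activities optional data.frame with columns `sample_id`,
#'   `ic50_agi`, `ic50_dpph`; reciprocals are computed and attached.
#' @return a validated `MetaboSet`.
#' @examples
#' sim <- simulateExtractStudy(seed = 1)
#' sim$mset
#' @export
MetaboSet <- function(responses, sampleData, featureData, activities = NULL) {
  responses <- as.matrix(responses)
  stopifnot(nrow(responses) == nrow(sampleData),
            ncol(responses) == nrow(featureData))
  storage.mode(responses) <- "double"
  rownames(responses) <- sampleData$sample_id
  colnames(responses) <- featureData$var_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(response = t(responses)),
    rowData = S4Vectors::DataFrame(featureData),
    colData = S4Vectors::DataFrame(sampleData, row.names = sampleData$sample_id))
  obj <- methods::new("MetaboSet", se)
  if (!is.null(activities)) obj <- attachActivities(obj, activities)
  obj
}

#' @describeIn MetaboSet compact display
#' @param object a `MetaboSet`
#' @export
setMethod("show", "MetaboSet", function(object) {
  cat("MetaboSet:", ncol(object), "samples x", nrow(object), "m/z features\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  solvent classes (% ethanol):",
      paste(sort(unique(cd$ethanol_pct)), collapse = ", "), "\n")
  cat("  activities attached:",
      if ("inv_agi" %in% colnames(cd)) "yes (AGI, DPPH)" else "no", "\n")
})

#' Scaled (unit-variance) response matrix
#'
#' Result of [uvScale()]: per-feature centred and scaled values plus the
#' centring/scaling vectors and any zero-variance features that were
#' dropped.
#'
#' @slot values samples-by-features matrix with column mean 0, sd 1.
#' @slot center,scale named per-feature column means / sample sds.
#' @slot dropped `var_id`s of zero-variance features removed before scaling.
#' @export
setClass("ScaledResponses",
  representation(values = "matrix", center = "numeric", scale = "numeric",
                 dropped = "character"))

#' @describeIn ScaledResponses compact display
#' @param object a `ScaledResponses`
#' @export
setMethod("show", "ScaledResponses", function(object) {
  cat("ScaledResponses:", nrow(object@values), "samples x",
      ncol(object@values), "features (UV-scaled)\n")
  if (length(object@dropped))
    cat("  dropped zero-variance:", paste(object@dropped, collapse = ", "), "\n")
})

#' Fitted latent-projection model
#'
#' A NIPALS projection model (PCA, PLS, OPLS or a discriminant variant).
#' Scores/weights/loadings refer to the predictive components; OPLS models
#' additionally carry the Y-orthogonal blocks. `r2y`/`q2` are cumulative
#' over components; `ssy` is the Y sum of squares explained per predictive
#' component (the VIP weighting).
#'
#' @slot method one of `"PCA"`, `"PLS"`, `"OPLS"`, `"PLS-DA"`, `"OPLS-DA"`.
#' @slot yNames names of the response columns (empty for PCA).
#' @slot W,P x-weights and x-loadings (p x A).
#' @slot C y-loadings (m x A).
#' @slot scores score matrix T (n x A).
#' @slot Wo,Po,orthoScores orthogonal blocks (zero-column for non-OPLS).
#' @slot r2x fraction of X variance explained per component.
#' @slot r2y,q2 cumulative explained / cross-validated predicted Y fraction.
#' @slot r2yPerTarget,q2PerTarget the same, per response column.
#' @slot ssy explained Y sum of squares per predictive component.
#' @slot featureNames,sampleNames dimension identities.
#' @slot yCenter,yScale response centring/scaling used for the fit.
#' @export
setClass("LatentModel",
  representation(method = "character", yNames = "character",
                 W = "matrix", P = "matrix", C = "matrix", scores = "matrix",
                 Wo = "matrix", Po = "matrix", orthoScores = "matrix",
                 r2x = "numeric", r2y = "numeric", q2 = "numeric",
                 r2yPerTarget = "numeric", q2PerTarget = "numeric",
                 ssy = "numeric", featureNames = "character",
                 sampleNames = "character",
                 yCenter = "numeric", yScale = "numeric"))

setValidity("LatentModel", function(object) {
  msg <- character(0)
  if (!object@method %in% c("PCA", "PLS", "OPLS", "PLS-DA", "OPLS-DA"))
    msg <- c(msg, "unknown method")
  Tm <- object@scores
  if (ncol(Tm) > 1) {
    g <- crossprod(Tm)
    off <- max(abs(g[upper.tri(g)]))
    if (off > 1e-6 * max(diag(g)))
      msg <- c(msg, "score columns are not mutually orthogonal")
  }
  if (length(object@r2y) && (object@r2y < -1e-8 || object@r2y > 1 + 1e-8))
    msg <- c(msg, "r2y outside [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn LatentModel compact display
#' @param object a `LatentModel`
#' @export
setMethod("show", "LatentModel", function(object) {
  cat("LatentModel:", object@method, "with", ncol(object@scores),
      "predictive component(s)")
  if (ncol(object@orthoScores)) cat(" +", ncol(object@orthoScores), "orthogonal")
  cat("\n")
  if (length(object@yNames))
    cat("  Y:", paste(object@yNames, collapse = ", "), "\n")
  if (length(object@r2y))
    cat(sprintf("  R2Y = %.3f, Q2 = %.3f\n", object@r2y, object@q2))
  else
    cat(sprintf("  R2X (cum) = %.3f\n", sum(object@r2x)))
})
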