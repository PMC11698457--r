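#' Accessors for MetaboSet and LatentModel
#'
#' `responses()` returns the samples-by-features response matrix (the
#' orientation every downstream computation uses), `sampleMeta()` and
#' `featureMeta()` the metadata data.frames, and `activities()` the
#' per-sample activity table. For fitted models, `scores()`, `xWeights()`,
#' `xLoadings()`, `yLoadings()` and `orthoScores()` expose the latent
#' blocks, and `r2y()` / `modelQ2()` the cumulative fit statistics.
#'
#' @param x a `MetaboSet` or `LatentModel`
#' @return matrix or data.frame, see details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))
#' @rdname accessors
#' @export
setMethod("responses", "MetaboSet", function(x)
  t(SummarizedExperiment::assay(x, "response")))

#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
#' @rdname accessors
#' @export
setMethod("sampleMeta", "MetaboSet", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname accessors
#' @export
setGeneric("featureMeta", function(x) standardGeneric("featureMeta"))
#' @rdname accessors
#' @export
setMethod("featureMeta", "MetaboSet", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))
#' @rdname accessors
#' @export
setMethod("activities", "MetaboSet", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  need <- c("ic50_agi", "ic50_dpph")
  if (!all(need %in% colnames(cd)))
    stop("no activities attached; see attachActivities()")
  cd[, c("sample_id", "ic50_agi", "ic50_dpph", "inv_agi", "inv_dpph")]
})

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setMethod("scores", "LatentModel", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("xWeights", function(x) standardGeneric("xWeights"))
#' @rdname accessors
#' @export
setMethod("xWeights", "LatentModel", function(x) x@W)

#' @rdname accessors
#' @export
setGeneric("xLoadings", function(x) standardGeneric("xLoadings"))
#' @rdname accessors
#' @export
setMethod("xLoadings", "LatentModel", function(x) x@P)

#' @rdname accessors
#' @export
setGeneric("yLoadings", function(x) standardGeneric("yLoadings"))
#' @rdname accessors
#' @export
setMethod("yLoadings", "LatentModel", function(x) x@C)

#' @rdname accessors
#' @export
setGeneric("orthoScores", function(x) standardGeneric("orthoScores"))
#' @rdname accessors
#' @export
setMethod("orthoScores", "LatentModel", function(x) x@orthoScores)

#' @rdname accessors
#' @export
setGeneric("r2y", function(x) standardGeneric("r2y"))
#' @rdname accessors
#' @export
setMethod("r2y", "LatentModel", function(x) x@r2y)

#' @rdname accessors
#' @export
setGeneric("modelQ2", function(x) standardGeneric("modelQ2"))
#' @rdname accessors
#' @export
setMethod("modelQ2", "LatentModel", function(x) x@q2)
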