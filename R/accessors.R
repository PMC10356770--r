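#' @include AllClasses.R
NULL

#' Accessors for FeatureTable and result objects
#'
#' `intensities()` returns the feature x sample intensity matrix,
#' `sampleData()`/`featureData()` the column/row metadata, `featureIds()` and
#' `sampleIds()` the dimnames. `occurrence()`, `testScores()`, `markerIds()`
#' and `fractions()` expose the corresponding slots of ensemble, marker-set
#' and variation-partitioning results.
#'
#' @param x a [FeatureTable-class], [EnsembleResult-class],
#'   [MarkerSet-class] or [VarpartResult-class] object.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setMethod("intensities", "FeatureTable", function(x) assay(x, "intensity"))

#' @rdname accessors
#' @export
setGeneric("intensities<-", function(x, value) standardGeneric("intensities<-"))

#' @rdname accessors
#' @export
setReplaceMethod("intensities", "FeatureTable", function(x, value) {
  assay(x, "intensity") <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setMethod("sampleData", "FeatureTable", function(x) colData(x))

#' @rdname accessors
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' @rdname accessors
#' @export
setMethod("featureData", "FeatureTable", function(x) rowData(x))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setMethod("featureIds", "FeatureTable", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("featureIds", "MarkerSet", function(x) x@featureIds)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "FeatureTable", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("occurrence", function(x) standardGeneric("occurrence"))

#' @rdname accessors
#' @export
setMethod("occurrence", "EnsembleResult", function(x) x@occurrence)

#' @rdname accessors
#' @export
setMethod("occurrence", "MarkerSet", function(x) x@occurrence)

#' @rdname accessors
#' @export
setGeneric("testScores", function(x) standardGeneric("testScores"))

#' @rdname accessors
#' @export
setMethod("testScores", "EnsembleResult", function(x) x@testScores)

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setMethod("fractions", "VarpartResult", function(x) x@fractions)

#' @rdname accessors
#' @export
setGeneric("chemoMarkerIds", function(x) standardGeneric("chemoMarkerIds"))

#' @rdname accessors
#' @export
setMethod("chemoMarkerIds", "GroundTruth", function(x) x@chemoMarkerIds)

#' @rdname accessors
#' @export
setGeneric("genoMarkerIds", function(x) standardGeneric("genoMarkerIds"))

#' @rdname accessors
#' @export
setMethod("genoMarkerIds", "GroundTruth", function(x) x@genoMarkerIds)

#' @rdname accessors
#' @export
setGeneric("classAssignments", function(x) standardGeneric("classAssignments"))

#' @rdname accessors
#' @export
setMethod("classAssignments", "DendrogramCut", function(x) x@classes)

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object), "features x", ncol(object), "samples\n")
  if ("batch" %in% colnames(colData(object)))
    cat("  batches:", paste(unique(colData(object)$batch), collapse = ", "), "\n")
  if ("chemotype" %in% colnames(colData(object)))
    cat("  chemotypes:", paste(levels(factor(colData(object)$chemotype)),
                               collapse = ", "), "\n")
  callNextMethod()
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth ledger\n")
  cat("  chemotype markers:", length(object@chemoMarkerIds),
      sprintf("(%d class-exclusive)", sum(!is.na(object@exclusiveClass))), "\n")
  cat("  genotype markers: ", length(object@genoMarkerIds), "\n")
  cat("  weak-blank features:", length(object@weakBlankIds), "\n")
})

setMethod("show", "ElasticNetModel", function(object) {
  cat("ElasticNetModel:", length(object@classes), "classes,",
      length(object@featureIds), "features\n")
  cat(sprintf("  alpha = %.4g, lambda = %.4g, nonzero = %d\n",
              object@alpha, object@lambda, sum(colSums(object@coefficients != 0) > 0)))
})

setMethod("show", "EnsembleResult", function(object) {
  cat("EnsembleResult:", length(object@testScores), "models,",
      ncol(object@selectionMatrix), "features,",
      length(object@classes), "classes\n")
  cat(sprintf("  mean test accuracy %.3f (sd %.3f)\n",
              mean(object@testScores), stats::sd(object@testScores)))
})

setMethod("show", "MarkerSet", function(object) {
  cat("MarkerSet:", length(object@featureIds), "markers (rule:",
      object@rule$type, "=", object@rule$value, ")\n")
  n <- min(5L, length(object@featureIds))
  if (n > 0)
    cat("  top:", paste(sprintf("%s(%d)", object@featureIds[seq_len(n)],
                                object@occurrence[seq_len(n)]), collapse = " "), "\n")
})

setMethod("show", "VarpartResult", function(object) {
  f <- object@fractions
  cat("VarpartResult (adjusted R-squared fractions)\n")
  cat(sprintf("  a (unique X1) = %.3f  p = %s\n", f["a"],
              format.pval(object@pValues["a"])))
  cat(sprintf("  c (unique X2) = %.3f  p = %s\n", f["c"],
              format.pval(object@pValues["c"])))
  cat(sprintf("  b (shared)    = %.3f   d (residual) = %.3f\n", f["b"], f["d"]))
})

setMethod("show", "DendrogramCut", function(object) {
  cat("DendrogramCut: k =", object@k, "classes over",
      length(object@classes), "entities\n")
  print(table(object@classes))
})
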