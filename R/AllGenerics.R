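#' @include AllClasses.R
NULL

#' Accessors for grid-backed objects
#'
#' \code{voxelData} returns the raw 3D array, \code{spacing} and
#' \code{origin} the physical grid geometry in mm, and \code{gridDim} the
#' voxel counts per axis.
#'
#' @param x An [ImageVolume-class] or [LabelMap-class] (or, where noted, an
#'   [Atlas-class] / [RcaTestCase-class]).
#' @return \code{voxelData}: array; \code{spacing}, \code{origin}: numeric
#'   length-3; \code{gridDim}: integer length-3.
#' @aliases voxelData spacing origin gridDim
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname grid-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname grid-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname grid-accessors
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@data)
#' @rdname grid-accessors
#' @export
setMethod("voxelData", "LabelMap", function(x) x@data)
#' @rdname grid-accessors
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname grid-accessors
#' @export
setMethod("spacing", "LabelMap", function(x) x@spacing)
#' @rdname grid-accessors
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)
#' @rdname grid-accessors
#' @export
setMethod("origin", "LabelMap", function(x) x@origin)
#' @rdname grid-accessors
#' @export
setMethod("gridDim", "ImageVolume", function(x) dim(x@data))
#' @rdname grid-accessors
#' @export
setMethod("gridDim", "LabelMap", function(x) dim(x@data))

#' Label-value table of a LabelMap
#' @param x A [LabelMap-class].
#' @return Named integer vector of class codes.
#' @export
setGeneric("labelValues", function(x) standardGeneric("labelValues"))
#' @rdname labelValues
#' @export
setMethod("labelValues", "LabelMap", function(x) x@labelValues)

#' Identifier, image and label accessors for atlases and test cases
#' @param x An [Atlas-class] or [RcaTestCase-class].
#' @return \code{atlasId}/\code{caseId}: character; the others return the
#'   corresponding component object.
#' @aliases atlasId caseId atlasImage atlasLabels predictedLabels gtLabels
#' @name case-accessors
NULL

#' @rdname case-accessors
#' @export
setGeneric("atlasId", function(x) standardGeneric("atlasId"))
#' @rdname case-accessors
#' @export
setMethod("atlasId", "Atlas", function(x) x@id)
#' @rdname case-accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname case-accessors
#' @export
setMethod("caseId", "RcaTestCase", function(x) x@id)
#' @rdname case-accessors
#' @export
setMethod("caseId", "RcaResult", function(x) x@caseId)
#' @rdname case-accessors
#' @export
setGeneric("atlasImage", function(x) standardGeneric("atlasImage"))
#' @rdname case-accessors
#' @export
setMethod("atlasImage", "Atlas", function(x) x@image)
#' @rdname case-accessors
#' @export
setMethod("atlasImage", "RcaTestCase", function(x) x@image)
#' @rdname case-accessors
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))
#' @rdname case-accessors
#' @export
setMethod("atlasLabels", "Atlas", function(x) x@labels)
#' @rdname case-accessors
#' @export
setGeneric("predictedLabels", function(x) standardGeneric("predictedLabels"))
#' @rdname case-accessors
#' @export
setMethod("predictedLabels", "RcaTestCase", function(x) x@predictedLabels)
#' @rdname case-accessors
#' @export
setGeneric("gtLabels", function(x) standardGeneric("gtLabels"))
#' @rdname case-accessors
#' @export
setMethod("gtLabels", "RcaTestCase", function(x) x@gtLabels)

#' Atomic classes of a ClassSpec
#' @param x A [ClassSpec-class].
#' @return Named integer vector of atomic class codes.
#' @export
setGeneric("atomicClasses", function(x) standardGeneric("atomicClasses"))
#' @rdname atomicClasses
#' @export
setMethod("atomicClasses", "ClassSpec", function(x) x@atomicClasses)

#' RcaResult accessors
#'
#' \code{predictedMetrics} returns the predicted ClassMetrics data frame
#' (rows LVC/LVM/RVC/AV/WH), \code{perReferenceMetrics} the full
#' per-reference metric table, and \code{bestReference} the winning
#' reference id for every defined (class, metric) slot.
#'
#' @param x An [RcaResult-class].
#' @return A data frame.
#' @aliases predictedMetrics perReferenceMetrics bestReference
#' @name rcaresult-accessors
NULL

#' @rdname rcaresult-accessors
#' @export
setGeneric("predictedMetrics", function(x) standardGeneric("predictedMetrics"))
#' @rdname rcaresult-accessors
#' @export
setMethod("predictedMetrics", "RcaResult", function(x) x@predicted)
#' @rdname rcaresult-accessors
#' @export
setGeneric("perReferenceMetrics",
           function(x) standardGeneric("perReferenceMetrics"))
#' @rdname rcaresult-accessors
#' @export
setMethod("perReferenceMetrics", "RcaResult", function(x) x@perReference)
#' @rdname rcaresult-accessors
#' @export
setGeneric("bestReference", function(x) standardGeneric("bestReference"))
#' @rdname rcaresult-accessors
#' @export
setMethod("bestReference", "RcaResult", function(x) x@bestReference)

#' Derived rates of a confusion matrix
#'
#' Positive class = good segmentation. A zero denominator yields \code{NA}.
#'
#' @param x A [ConfusionStats-class].
#' @return A single numeric value (or \code{NA}).
#' @aliases accuracy tpr fpr
#' @name confusion-rates
NULL

#' @rdname confusion-rates
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname confusion-rates
#' @export
setMethod("accuracy", "ConfusionStats", function(x) {
  n <- x@tp + x@fp + x@tn + x@fn
  if (n == 0L) NA_real_ else (x@tp + x@tn) / n
})
#' @rdname confusion-rates
#' @export
setGeneric("tpr", function(x) standardGeneric("tpr"))
#' @rdname confusion-rates
#' @export
setMethod("tpr", "ConfusionStats", function(x) {
  d <- x@tp + x@fn
  if (d == 0L) NA_real_ else x@tp / d
})
#' @rdname confusion-rates
#' @export
setGeneric("fpr", function(x) standardGeneric("fpr"))
#' @rdname confusion-rates
#' @export
setMethod("fpr", "ConfusionStats", function(x) {
  d <- x@fp + x@tn
  if (d == 0L) NA_real_ else x@fp / d
})
#' @rdname confusion-rates
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname confusion-rates
#' @export
setMethod("confusionCounts", "ConfusionStats", function(x)
  c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %dx%dx%d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = "/")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelMap %dx%dx%d voxels, spacing %s mm\n", d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x")))
  tab <- table(factor(object@data, levels = object@labelValues))
  names(tab) <- names(object@labelValues)[
    match(names(tab), as.character(object@labelValues))]
  cat("  voxels per class:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

setMethod("show", "Atlas", function(object) {
  cat(sprintf("Atlas '%s'\n", object@id))
  show(object@image)
  show(object@labels)
})

setMethod("show", "RcaTestCase", function(object) {
  cat(sprintf("RcaTestCase '%s' (%s ground truth)\n", object@id,
              if (is.null(object@gtLabels)) "without" else "with"))
  show(object@image)
})

setMethod("show", "SpatialTransform", function(object) {
  cat(sprintf("SpatialTransform kind='%s', translation (%.3f, %.3f, %.3f) mm",
              object@kind, object@translation[1], object@translation[2],
              object@translation[3]))
  if (!is.null(object@displacementField)) {
    m <- sqrt(rowSums(matrix(object@displacementField, ncol = 3L)^2))
    cat(sprintf(", field mean |d| = %.3f mm", mean(m)))
  }
  cat("\n")
})

setMethod("show", "ConfusionStats", function(object) {
  cat(sprintf(
    "ConfusionStats (positive = good): TP=%d FP=%d TN=%d FN=%d\n",
    object@tp, object@fp, object@tn, object@fn))
  cat(sprintf("  accuracy=%.4g TPR=%.4g FPR=%.4g\n",
              accuracy(object), tpr(object), fpr(object)))
})

setMethod("show", "RcaResult", function(object) {
  cat(sprintf("RcaResult for case '%s' (%d references)\n", object@caseId,
              object@nReferencesUsed))
  print(object@predicted, row.names = FALSE, digits = 4)
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})
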