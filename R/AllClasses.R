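#' @include rcaqc-package.R
NULL

GEOM_TOL <- 1e-6

.checkGeometry <- function(object) {
  msg <- character()
  d <- dim(object@data)
  if (is.null(d) || length(d) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite values (mm)")
  msg
}

#' ImageVolume: a 3D scalar image on an axis-aligned anisotropic grid
#'
#' The basic intensity container: a 3D array of finite scalars plus the
#' physical grid geometry. The voxel centre of (1-based) index \code{(i,j,k)}
#' sits at \code{origin + ((i-1)*sx, (j-1)*sy, (k-1)*sz)} in physical mm.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot spacing Numeric length-3, voxel size in mm per axis; strictly positive.
#' @slot origin Numeric length-3, physical coordinate (mm) of voxel (1,1,1).
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- .checkGeometry(object)
    if (length(msg) == 0L && !all(is.finite(object@data)))
      msg <- c(msg, "all intensities must be finite")
    if (length(msg)) msg else TRUE
  })

#' LabelMap: a 3D integer segmentation on the same grid model as ImageVolume
#'
#' Voxel values are small non-negative integer class codes. The default
#' cardiac convention is 0 = background, 1 = LV cavity (LVC), 2 = LV
#' myocardium (LVM), 3 = RV cavity (RVC). Membership of every voxel in the
#' declared label set is checked by [validateAtlas()] (reported, not raised)
#' and enforced at file ingest by [readLabels()].
#'
#' @slot data 3D integer array.
#' @slot spacing,origin As for [ImageVolume-class].
#' @slot labelValues Named integer vector mapping class names to codes,
#'   including \code{background = 0}.
#' @export
setClass("LabelMap",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 labelValues = "integer"),
  validity = function(object) {
    msg <- .checkGeometry(object)
    if (!is.integer(object@data))
      msg <- c(msg, "label data must be stored as integers")
    if (anyNA(object@data))
      msg <- c(msg, "label data must not contain NA")
    if (is.null(names(object@labelValues)) || anyDuplicated(object@labelValues))
      msg <- c(msg, "labelValues must be a named vector of distinct codes")
    if (length(msg)) msg else TRUE
  })

setClassUnion("LabelMapOrNULL", c("LabelMap", "NULL"))

#' Atlas: a verified image-segmentation pair used as an RCA reference
#'
#' @slot id Character identifier.
#' @slot image The [ImageVolume-class].
#' @slot labels The verified [LabelMap-class] on the identical grid.
#' @export
setClass("Atlas",
  representation(id = "character", image = "ImageVolume", labels = "LabelMap"),
  validity = function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "id must be a single non-empty string")
    if (!sameGrid(object@image, object@labels))
      msg <- c(msg, "image and labels must share one grid")
    if (length(msg)) msg else TRUE
  })

#' RcaTestCase: a test image with the segmentation under assessment
#'
#' @slot id Character identifier.
#' @slot image The test [ImageVolume-class].
#' @slot predictedLabels The automatic segmentation whose quality is assessed.
#' @slot gtLabels Optional ground-truth [LabelMap-class] for validation mode.
#' @export
setClass("RcaTestCase",
  representation(id = "character", image = "ImageVolume",
                 predictedLabels = "LabelMap", gtLabels = "LabelMapOrNULL"),
  validity = function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "id must be a single non-empty string")
    if (!sameGrid(object@image, object@predictedLabels))
      msg <- c(msg, "predictedLabels must share the image grid")
    if (!is.null(object@gtLabels) && !sameGrid(object@image, object@gtLabels))
      msg <- c(msg, "gtLabels must share the image grid")
    if (length(msg)) msg else TRUE
  })

#' ClassSpec: the atomic segmentation classes and their derived summaries
#'
#' Holds the ordered atomic classes (default LVC = 1, LVM = 2, RVC = 3).
#' Two summaries are derived everywhere: \code{WH}, the whole-heart union of
#' all atomic labels evaluated as one binary mask, and \code{AV}, the
#' unweighted mean over the defined per-class metric values.
#'
#' @slot atomicClasses Named integer vector of distinct non-zero codes.
#' @export
setClass("ClassSpec",
  representation(atomicClasses = "integer"),
  validity = function(object) {
    msg <- character()
    v <- object@atomicClasses
    if (length(v) < 1L || is.null(names(v)) || any(!nzchar(names(v))))
      msg <- c(msg, "atomicClasses must be a named integer vector")
    if (any(v == 0L) || anyDuplicated(v) || anyNA(v))
      msg <- c(msg, "atomic labels must be distinct non-zero integers")
    if (any(names(v) %in% c("AV", "WH", "background")))
      msg <- c(msg, "class names AV/WH/background are reserved")
    if (length(msg)) msg else TRUE
  })

#' SpatialTransform: translation and/or dense displacement on the fixed grid
#'
#' The point mapping moving -> fixed is \code{p -> p + translation}; a
#' deformable transform additionally carries a displacement field defined on
#' the fixed (test) grid, in mm, used as a pull-back offset when resampling
#' the moving image (sample point \code{x - translation + d(x)}).
#'
#' @slot kind One of \code{"identity"}, \code{"translation"},
#'   \code{"deformable"}.
#' @slot translation Numeric length-3, mm.
#' @slot displacementField \code{NULL} or a 4D array \code{c(dim, 3)} of
#'   per-voxel offsets in mm on the fixed grid.
#' @slot fixedSpacing,fixedOrigin Geometry of the grid the field lives on.
#' @slot provenance List recording backend, parameters and seed.
#' @slot warning Logical: \code{TRUE} when the optimiser returned a
#'   no-improvement fallback.
#' @export
setClass("SpatialTransform",
  representation(kind = "character", translation = "numeric",
                 displacementField = "ANY", fixedSpacing = "numeric",
                 fixedOrigin = "numeric", provenance = "list",
                 warning = "logical"),
  prototype(kind = "identity", translation = c(0, 0, 0),
            displacementField = NULL, fixedSpacing = c(1, 1, 1),
            fixedOrigin = c(0, 0, 0), provenance = list(), warning = FALSE),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("identity", "translation", "deformable"))
      msg <- c(msg, "kind must be identity/translation/deformable")
    if (length(object@translation) != 3L || any(!is.finite(object@translation)))
      msg <- c(msg, "translation must be three finite values (mm)")
    if (object@kind == "identity" &&
        (any(object@translation != 0) || !is.null(object@displacementField)))
      msg <- c(msg, "identity transform must have zero translation and no field")
    if (!is.null(object@displacementField)) {
      f <- object@displacementField
      if (!is.array(f) || length(dim(f)) != 4L || dim(f)[4] != 3L)
        msg <- c(msg, "displacementField must be a c(nx,ny,nz,3) array")
      else if (!all(is.finite(f)))
        msg <- c(msg, "displacement components must be finite")
    }
    if (length(msg)) msg else TRUE
  })

#' RegistrationConfig: backend and parameters of the registration stage
#'
#' @slot backend \code{"identity"}, \code{"translation_only"} or
#'   \code{"deformable"} (multi-resolution demons-style registration).
#' @slot similarity Similarity driving the deformable stage; \code{"ssd"}
#'   (sum of squared differences on min-max-normalised intensities).
#' @slot pyramidLevels Integer >= 1, resolution levels (factor 2 per level).
#' @slot smoothingSigma Gaussian regularisation sigma in mm per axis
#'   (length 1 or 3); \code{NA} selects twice the test-grid voxel spacing.
#' @slot maxIterations Iterations per pyramid level.
#' @slot seed Integer recorded in provenance (the algorithm is deterministic).
#' @export
setClass("RegistrationConfig",
  representation(backend = "character", similarity = "character",
                 pyramidLevels = "integer", smoothingSigma = "numeric",
                 maxIterations = "integer", seed = "integer"),
  prototype(backend = "deformable", similarity = "ssd", pyramidLevels = 3L,
            smoothingSigma = NA_real_, maxIterations = 50L, seed = 1L),
  validity = function(object) {
    msg <- character()
    if (!object@backend %in% c("identity", "translation_only", "deformable"))
      msg <- c(msg, "unknown backend")
    if (!identical(object@similarity, "ssd"))
      msg <- c(msg, "similarity must be 'ssd'")
    if (object@pyramidLevels < 1L) msg <- c(msg, "pyramidLevels must be >= 1")
    if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
    if (!length(object@smoothingSigma) %in% c(1L, 3L))
      msg <- c(msg, "smoothingSigma must have length 1 or 3")
    if (any(!is.na(object@smoothingSigma) & object@smoothingSigma <= 0))
      msg <- c(msg, "smoothingSigma must be positive")
    if (length(msg)) msg else TRUE
  })

#' QualityThresholds: the good/poor decision boundaries
#'
#' A segmentation is classified good when its DSC is at least
#' \code{dscGoodMin} (default 0.7) or, for the surface criterion, when its
#' MSD is at most \code{msdGoodMax} mm (default 2.0); both boundaries are
#' inclusive on the good side.
#'
#' @slot dscGoodMin Numeric in (0, 1).
#' @slot msdGoodMax Positive numeric, mm.
#' @export
setClass("QualityThresholds",
  representation(dscGoodMin = "numeric", msdGoodMax = "numeric"),
  prototype(dscGoodMin = 0.7, msdGoodMax = 2.0),
  validity = function(object) {
    msg <- character()
    if (object@dscGoodMin <= 0 || object@dscGoodMin >= 1)
      msg <- c(msg, "dscGoodMin must lie in (0, 1)")
    if (object@msdGoodMax <= 0) msg <- c(msg, "msdGoodMax must be positive")
    if (length(msg)) msg else TRUE
  })

#' ConfusionStats: good/poor confusion counts with derived rates
#'
#' Positive class = good segmentation, so TPR is the sensitivity for good
#' and FPR the rate of poor segmentations passed as good. Derived rates with
#' a zero denominator are undefined (\code{NA}).
#'
#' @slot tp,fp,tn,fn Non-negative integer counts.
#' @export
setClass("ConfusionStats",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer"),
  validity = function(object) {
    cnt <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(is.na(cnt)) || any(cnt < 0L))
      "counts must be non-negative integers"
    else TRUE
  })

#' RcaResult: the per-case output of reverse classification accuracy
#'
#' @slot caseId Character identifier of the test case.
#' @slot perReference Data frame with one row per (reference, class):
#'   columns \code{reference_id}, \code{class}, \code{dsc}, \code{msd},
#'   \code{rmsd}, \code{hd}, \code{reg_warning}.
#' @slot predicted Data frame of predicted metrics (rows LVC/LVM/RVC/AV/WH,
#'   columns class/dsc/msd/rmsd/hd): best value per (class, metric) over the
#'   references (max for DSC, min for distances), AV recomputed as the mean
#'   of the defined predicted atomic values.
#' @slot bestReference Data frame (class, metric, reference_id) naming the
#'   winning reference for every defined predicted slot.
#' @slot nReferencesUsed Integer number of references contributing rows.
#' @slot warnings Character vector of per-case warnings.
#' @export
setClass("RcaResult",
  representation(caseId = "character", perReference = "data.frame",
                 predicted = "data.frame", bestReference = "data.frame",
                 nReferencesUsed = "integer", warnings = "character"))
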