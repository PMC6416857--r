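#' @include AllClasses.R
NULL

DEFAULT_LABEL_VALUES <- c(background = 0L, LVC = 1L, LVM = 2L, RVC = 3L)

#' Construct an ImageVolume
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Voxel size in mm per axis (length 3, strictly positive).
#' @param origin Physical coordinate (mm) of the first voxel centre.
#' @return An [ImageVolume-class].
#' @examples
#' img <- imageVolume(array(0, c(4, 4, 2)), spacing = c(1.25, 1.25, 2))
#' spacing(img)
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabelMap
#'
#' @inheritParams imageVolume
#' @param data 3D array of integer class codes.
#' @param labelValues Named integer vector mapping class names to codes;
#'   defaults to the cardiac convention background/LVC/LVM/RVC = 0/1/2/3.
#' @return A [LabelMap-class].
#' @export
labelMap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     labelValues = DEFAULT_LABEL_VALUES) {
  if (is.double(data)) {
    if (max(abs(data - round(data))) > 1e-6)
      stop("label data contains non-integer values")
    data <- round(data)
  }
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin),
      labelValues = structure(as.integer(labelValues),
                              names = names(labelValues)))
}

#' Construct an Atlas (verified image-segmentation pair)
#'
#' @param id Character identifier.
#' @param image An [ImageVolume-class].
#' @param labels A [LabelMap-class] on the identical grid.
#' @return An [Atlas-class].
#' @export
atlas <- function(id, image, labels)
  new("Atlas", id = as.character(id), image = image, labels = labels)

#' Construct a test case (image + segmentation under assessment)
#'
#' @param id Character identifier.
#' @param image The test [ImageVolume-class].
#' @param predictedLabels The automatic segmentation to be quality-assessed.
#' @param gtLabels Optional ground truth for validation mode.
#' @return An [RcaTestCase-class].
#' @export
rcaTestCase <- function(id, image, predictedLabels, gtLabels = NULL)
  new("RcaTestCase", id = as.character(id), image = image,
      predictedLabels = predictedLabels, gtLabels = gtLabels)

#' Construct a ClassSpec
#'
#' @param atomicClasses Named integer vector of distinct non-zero codes, in
#'   reporting order.
#' @return A [ClassSpec-class].
#' @export
classSpec <- function(atomicClasses = c(LVC = 1L, LVM = 2L, RVC = 3L))
  new("ClassSpec", atomicClasses = structure(as.integer(atomicClasses),
                                             names = names(atomicClasses)))

#' The default cardiac three-class specification (LVC/LVM/RVC = 1/2/3)
#' @return A [ClassSpec-class].
#' @export
defaultClassSpec <- function() classSpec()

#' Do two grid-backed objects share the same grid?
#'
#' Identical voxel counts, and spacing and origin equal within 1e-6 mm.
#'
#' @param a,b [ImageVolume-class] or [LabelMap-class] objects.
#' @return Logical scalar.
#' @export
sameGrid <- function(a, b) {
  identical(dim(a@data), dim(b@data)) &&
    all(abs(a@spacing - b@spacing) <= GEOM_TOL) &&
    all(abs(a@origin - b@origin) <= GEOM_TOL)
}

.stopIfGridMismatch <- function(a, b) {
  if (!sameGrid(a, b))
    stop("inputs are defined on incompatible grids")
  invisible(TRUE)
}

#' Validate an atlas against a class specification
#'
#' Checks the structural invariants of an [Atlas-class] and reports every
#' violation as a character message instead of raising: unknown label codes,
#' geometry mismatches between image and labels, non-finite intensities, and
#' atomic classes with zero voxels. Side-effect free and idempotent.
#'
#' @param x An [Atlas-class].
#' @param spec A [ClassSpec-class].
#' @return Character vector of violations; empty when the atlas is valid.
#' @examples
#' a <- generatePhantom(phantomSpec(seed = 1))
#' validateAtlas(a)   # character(0)
#' @export
validateAtlas <- function(x, spec = defaultClassSpec()) {
  report <- character()
  img <- x@image
  lab <- x@labels
  if (!sameGrid(img, lab))
    report <- c(report, "image and labels do not share one grid")
  if (!all(is.finite(img@data)))
    report <- c(report, "image contains non-finite intensities")
  known <- sort(unique(c(0L, as.integer(spec@atomicClasses),
                         as.integer(lab@labelValues))))
  present <- sort(unique(as.vector(lab@data)))
  unknown <- setdiff(present, known)
  for (u in unknown)
    report <- c(report, sprintf("unknown label %d", u))
  for (nm in names(spec@atomicClasses)) {
    code <- spec@atomicClasses[[nm]]
    if (!any(lab@data == code))
      report <- c(report, sprintf("empty class %s", nm))
  }
  if (all(lab@data == 0L))
    report <- c(report, "labels contain no non-background voxel")
  report
}
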