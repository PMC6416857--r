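#' @include core-model.R
NULL

REPORT_SCHEMA_VERSION <- "1.0"

# NIfTI files may drop trailing singleton dimensions; restore a 3D shape
.dim3 <- function(img) {
  d <- dim(img)
  if (is.null(d)) d <- length(img)
  as.integer(c(d, rep(1L, 3 - length(d)))[1:3])
}

.niftiGeometry <- function(img) {
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  # column norms of the xform carry the voxel spacing even when the pixdim
  # header field was left at its default
  sp <- sqrt(colSums(rot^2))
  sp[sp == 0] <- abs(RNifti::pixdim(img)[1:3])[sp == 0]
  # axis-aligned check: off-diagonal rotation terms must vanish
  scale <- max(abs(diag(rot)), 1e-8)
  diagOnly <- all(abs(rot[row(rot) != col(rot)]) < 1e-4 * scale)
  if (!diagOnly)
    warning(paste("oblique or permuted NIfTI orientation detected;",
                  "the grid is treated as axis-aligned with header voxel",
                  "spacing - verify registration inputs"))
  origin <- xf[1:3, 4]
  list(spacing = abs(sp), origin = as.numeric(origin))
}

#' Read a NIfTI-1 intensity volume
#'
#' Voxel spacing is taken from the header xform scale (falling back to
#' pixdim) and the origin from the xform translation. Oblique (rotated) orientations are not supported as
#' such: a warning is emitted and the data grid is treated as axis-aligned.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @return An [ImageVolume-class].
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  g <- .niftiGeometry(img)
  dat <- array(as.numeric(img), .dim3(img))
  imageVolume(dat, spacing = g$spacing, origin = g$origin)
}

#' Read a NIfTI-1 label map
#'
#' Values must be losslessly castable to integers and every value must be
#' declared in \code{labelValues}; otherwise an error names the offending
#' value.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @param labelValues Named integer class map (default cardiac 0/1/2/3).
#' @return A [LabelMap-class].
#' @export
readLabels <- function(path, labelValues = DEFAULT_LABEL_VALUES) {
  img <- RNifti::readNifti(path)
  g <- .niftiGeometry(img)
  dat <- array(as.numeric(img), .dim3(img))
  if (max(abs(dat - round(dat))) > 1e-6)
    stop("label file contains non-integer data: ", path)
  dat <- round(dat)
  present <- sort(unique(as.vector(dat)))
  unknown <- setdiff(present, as.integer(labelValues))
  if (length(unknown))
    stop(sprintf("label file contains value(s) %s not covered by the class map",
                 paste(unknown, collapse = ", ")))
  labelMap(dat, spacing = g$spacing, origin = g$origin,
           labelValues = labelValues)
}

.asNiftiWithGeometry <- function(data, spacing, origin, datatype) {
  img <- RNifti::asNifti(data, datatype = datatype)
  mat <- diag(4)
  diag(mat)[1:3] <- spacing
  mat[1:3, 4] <- origin
  RNifti::`sform<-`(img, structure(mat, code = 2L))
}

#' Write an ImageVolume to NIfTI-1
#'
#' @param x An [ImageVolume-class].
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
writeVolume <- function(x, path) {
  img <- .asNiftiWithGeometry(x@data, x@spacing, x@origin, "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a LabelMap to NIfTI-1 (unsigned 8-bit)
#'
#' @param x A [LabelMap-class].
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
writeLabels <- function(x, path) {
  if (any(x@data < 0L) || any(x@data > 255L))
    stop("labels outside the unsigned 8-bit range cannot be written")
  img <- .asNiftiWithGeometry(x@data, x@spacing, x@origin, "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a per-case RCA report as JSON
#'
#' The report contains the predicted ClassMetrics, the winning reference
#' per (class, metric), and the full per-reference metric table, so a
#' per-case audit panel can be reconstructed from the file alone.
#'
#' @param result An [RcaResult-class].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
writeCaseReport <- function(result, path) {
  payload <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    case_id = result@caseId,
    n_references_used = result@nReferencesUsed,
    predicted = result@predicted,
    best_reference = result@bestReference,
    per_reference = result@perReference,
    warnings = result@warnings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 6,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Read back a per-case JSON report
#' @param path Path written by [writeCaseReport()].
#' @return List with the report fields (data frames restored).
#' @export
readCaseReport <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' Write a batch summary table as CSV
#'
#' A header comment line carries the schema version; columns are written
#' exactly as present in the summary data frame, floats at six significant
#' digits.
#'
#' @param rows Data frame (e.g. the \code{summary} element of
#'   [rcaBatch()]); may be empty.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeBatchReport <- function(rows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rcaqc batch report schema %s",
                     REPORT_SCHEMA_VERSION), con)
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], signif, digits = 6L)
  write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: \code{reference_dir}, \code{output_dir},
#'   \code{label_values} (named class map), \code{registration} (fields of
#'   [registrationConfig()]), \code{thresholds} (\code{dsc_good_min},
#'   \code{msd_good_max}), \code{seed}. Missing sections fall back to the
#'   package defaults.
#'
#' @param path YAML file path.
#' @return List with \code{referenceDir}, \code{outputDir},
#'   \code{labelValues}, \code{regConfig}, \code{thresholds}, \code{seed}.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  lv <- if (!is.null(cfg$label_values))
    structure(as.integer(unlist(cfg$label_values)),
              names = names(cfg$label_values))
  else DEFAULT_LABEL_VALUES
  reg <- cfg$registration
  regConfig <- registrationConfig(
    backend = if (is.null(reg$backend)) "deformable" else reg$backend,
    pyramidLevels = if (is.null(reg$pyramid_levels)) 3L
                    else as.integer(reg$pyramid_levels),
    smoothingSigma = if (is.null(reg$smoothing_sigma)) NA_real_
                     else as.numeric(reg$smoothing_sigma),
    maxIterations = if (is.null(reg$max_iterations)) 50L
                    else as.integer(reg$max_iterations),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
  th <- cfg$thresholds
  thresholds <- qualityThresholds(
    dscGoodMin = if (is.null(th$dsc_good_min)) 0.7 else th$dsc_good_min,
    msdGoodMax = if (is.null(th$msd_good_max)) 2.0 else th$msd_good_max)
  list(referenceDir = cfg$reference_dir, outputDir = cfg$output_dir,
       labelValues = lv, regConfig = regConfig, thresholds = thresholds,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}
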