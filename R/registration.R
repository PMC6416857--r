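#' @include core-model.R
NULL

#' Construct a registration configuration
#'
#' @param backend \code{"identity"}, \code{"translation_only"} or
#'   \code{"deformable"}. The deformable backend is a deterministic
#'   multi-resolution demons-style registration: an intensity-difference
#'   force field with per-iteration Gaussian regularisation, driven by SSD
#'   on min-max-normalised intensities.
#' @param similarity Only \code{"ssd"} is implemented.
#' @param pyramidLevels Number of resolution levels (downsampling factor 2
#'   per level; per-axis factors are clamped so coarse grids keep at least
#'   four voxels per axis).
#' @param smoothingSigma Gaussian regularisation sigma in mm (length 1 or
#'   3); \code{NA} selects twice the test-grid voxel spacing per axis.
#' @param maxIterations Iterations per pyramid level.
#' @param seed Integer recorded in transform provenance.
#' @return A [RegistrationConfig-class].
#' @export
registrationConfig <- function(backend = c("deformable", "translation_only",
                                           "identity"),
                               similarity = "ssd", pyramidLevels = 3L,
                               smoothingSigma = NA_real_,
                               maxIterations = 50L, seed = 1L) {
  new("RegistrationConfig", backend = match.arg(backend),
      similarity = similarity, pyramidLevels = as.integer(pyramidLevels),
      smoothingSigma = as.numeric(smoothingSigma),
      maxIterations = as.integer(maxIterations), seed = as.integer(seed))
}

#' The identity spatial transform
#' @return A [SpatialTransform-class] of kind \code{"identity"}.
#' @export
identityTransform <- function() new("SpatialTransform")

#' Intensity-weighted centre of mass of an image
#'
#' Intensities are shifted so their minimum is zero before weighting, and
#' the weighted mean of the voxel-centre physical coordinates is returned.
#' A constant non-zero image yields the geometric grid centre; an all-zero
#' image is degenerate and raises an error.
#'
#' @param image An [ImageVolume-class].
#' @return Numeric length-3 physical point in mm.
#' @export
centerOfMass <- function(image) {
  w <- image@data - min(image@data)
  tot <- sum(w)
  d <- dim(w)
  sx <- image@spacing
  o <- image@origin
  if (tot <= 0) {
    if (all(image@data == 0))
      stop("degenerate image: all intensities are zero")
    # constant non-zero image: centre of mass is the geometric centre
    return(o + (d - 1) / 2 * sx)
  }
  # marginal sums avoid materialising coordinate arrays
  mx <- rowSums(w, dims = 1L)
  my <- rowSums(aperm(w, c(2L, 1L, 3L)), dims = 1L)
  mz <- rowSums(aperm(w, c(3L, 1L, 2L)), dims = 1L)
  c(o[1] + sum((seq_len(d[1]) - 1) * sx[1] * mx) / tot,
    o[2] + sum((seq_len(d[2]) - 1) * sx[2] * my) / tot,
    o[3] + sum((seq_len(d[3]) - 1) * sx[3] * mz) / tot)
}

#' Centre-of-mass translation aligning a moving image to a fixed image
#'
#' The rigid pre-alignment step: a pure translation
#' \code{CoM(fixed) - CoM(moving)} (no rotation), so that applying the
#' transform to the moving image's centre of mass yields the fixed image's
#' centre of mass exactly.
#'
#' @param fixed,moving [ImageVolume-class] objects.
#' @return A [SpatialTransform-class] of kind \code{"translation"}.
#' @export
comTranslation <- function(fixed, moving) {
  t <- centerOfMass(fixed) - centerOfMass(moving)
  new("SpatialTransform", kind = "translation", translation = t,
      provenance = list(backend = "com_translation"))
}

.resolveSigma <- function(config, spacingFixed) {
  s <- config@smoothingSigma
  if (length(s) == 1L) s <- rep(s, 3L)
  ifelse(is.na(s), 2 * spacingFixed, s)
}

.normalise01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(array(0, dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

.downsampleGeom <- function(dim, spacing, origin, f) {
  list(dim = dim %/% f, spacing = spacing * f,
       origin = origin + (f - 1) / 2 * spacing)
}

.ssd <- function(fixedData, warped) mean((fixedData - warped)^2)

.warpRaw <- function(data, sgeom, tgeom, translation, field, nearest, pad,
                     clampEdge = FALSE) {
  v <- cpp_warp(as.numeric(data), as.integer(sgeom$dim),
                as.numeric(sgeom$spacing), as.numeric(sgeom$origin),
                as.integer(tgeom$dim), as.numeric(tgeom$spacing),
                as.numeric(tgeom$origin), as.numeric(translation),
                if (is.null(field)) NULL else as.numeric(field),
                nearest, pad, clampEdge)
  array(v, tgeom$dim)
}

.geomOf <- function(x) list(dim = dim(x@data), spacing = x@spacing,
                            origin = x@origin)

#' Deformable registration of a moving image to a fixed image
#'
#' Runs the configured backend starting from \code{init} (an identity or
#' translation transform). The \code{"identity"} and \code{"translation_only"}
#' backends return \code{init} unchanged; \code{"deformable"} estimates a
#' dense displacement field on the fixed grid with a multi-resolution
#' demons-style scheme. The returned transform never has a worse SSD than
#' \code{init} alone: if the optimisation fails to improve the similarity
#' the field is dropped and the transform is flagged with a warning.
#' Deterministic for a fixed configuration.
#'
#' @param fixed,moving [ImageVolume-class] objects (fixed = test image,
#'   moving = reference image).
#' @param init A [SpatialTransform-class] of kind identity or translation.
#' @param config A [RegistrationConfig-class].
#' @return A [SpatialTransform-class] defined on the fixed grid.
#' @export
deformableRegister <- function(fixed, moving, init = identityTransform(),
                               config = registrationConfig()) {
  if (!init@kind %in% c("identity", "translation"))
    stop("init must be an identity or translation transform")
  validObject(config)
  if (config@backend %in% c("identity", "translation_only"))
    return(init)

  fgeom <- .geomOf(fixed)
  mgeom <- .geomOf(moving)
  F0 <- .normalise01(fixed@data)
  M0 <- .normalise01(moving@data)
  trans <- init@translation
  sigmaMM <- .resolveSigma(config, fixed@spacing)

  levels <- config@pyramidLevels
  field <- NULL # coarse-level field carried up the pyramid, mm
  prevGeom <- NULL
  for (lev in seq(levels, 1L)) {
    f2 <- 2^(lev - 1L)
    fac <- pmax(1L, pmin(as.integer(f2), fgeom$dim %/% 4L))
    if (all(fac == 1L) && lev > 1L) next
    lg <- .downsampleGeom(fgeom$dim, fgeom$spacing, fgeom$origin, fac)
    # both images are block-averaged to the level's scale so the SSD force
    # compares like with like
    Fl <- if (all(fac == 1L)) F0 else
      cpp_block_mean(as.numeric(F0), as.integer(fgeom$dim), as.integer(fac))
    mfac <- pmax(1L, pmin(as.integer(f2), mgeom$dim %/% 4L))
    mg <- .downsampleGeom(mgeom$dim, mgeom$spacing, mgeom$origin, mfac)
    Ml <- if (all(mfac == 1L)) M0 else
      cpp_block_mean(as.numeric(M0), as.integer(mgeom$dim), as.integer(mfac))
    # light pre-smoothing suppresses voxel noise in the force field
    Fl <- cpp_smooth_volume(as.numeric(Fl), as.integer(lg$dim),
                            rep(0.7, 3))
    Ml <- cpp_smooth_volume(as.numeric(Ml), as.integer(mg$dim),
                            rep(0.7, 3))
    if (is.null(field)) {
      fieldL <- numeric(3 * prod(lg$dim))
    } else {
      # resample each field component from the previous level's grid
      n <- prod(lg$dim)
      fieldL <- numeric(3 * n)
      for (c in 1:3) {
        comp <- array(field[((c - 1) * prod(prevGeom$dim) + 1):
                            (c * prod(prevGeom$dim))], prevGeom$dim)
        fieldL[((c - 1) * n + 1):(c * n)] <-
          .warpRaw(comp, prevGeom, lg, c(0, 0, 0), NULL, FALSE, 0,
                   clampEdge = TRUE)
      }
    }
    sigmaVox <- sigmaMM / lg$spacing
    stepCap <- min(lg$spacing)
    field <- cpp_demons(as.numeric(Fl), as.integer(lg$dim),
                        as.numeric(lg$spacing), as.numeric(lg$origin),
                        as.numeric(Ml), as.integer(mg$dim),
                        as.numeric(mg$spacing), as.numeric(mg$origin),
                        as.numeric(trans), fieldL,
                        config@maxIterations, as.numeric(sigmaVox), stepCap,
                        mean(lg$spacing), 0.005)
    prevGeom <- lg
  }

  fieldArr <- array(field, c(fgeom$dim, 3L))
  warpedInit <- .warpRaw(M0, mgeom, fgeom, trans, NULL, FALSE, 0)
  warpedFinal <- .warpRaw(M0, mgeom, fgeom, trans, fieldArr, FALSE, 0)
  warn <- FALSE
  if (.ssd(F0, warpedFinal) > .ssd(F0, warpedInit)) {
    # no-worsening contract: fall back to the initial transform
    fieldArr[] <- 0
    warn <- TRUE
  }
  new("SpatialTransform", kind = "deformable", translation = trans,
      displacementField = fieldArr, fixedSpacing = fgeom$spacing,
      fixedOrigin = fgeom$origin,
      provenance = list(backend = "demons", similarity = config@similarity,
                        pyramidLevels = config@pyramidLevels,
                        maxIterations = config@maxIterations,
                        smoothingSigmaMM = sigmaMM, seed = config@seed),
      warning = warn)
}

.checkFieldGrid <- function(transform, tgeom) {
  if (is.null(transform@displacementField)) return(invisible(TRUE))
  fd <- dim(transform@displacementField)[1:3]
  if (!identical(as.integer(fd), as.integer(tgeom$dim)) ||
      any(abs(transform@fixedSpacing - tgeom$spacing) > GEOM_TOL) ||
      any(abs(transform@fixedOrigin - tgeom$origin) > GEOM_TOL))
    stop("transform displacement field is not defined on the target grid")
  invisible(TRUE)
}

#' Warp a label map onto a target grid
#'
#' Nearest-neighbour sampling only (labels are never interpolated);
#' out-of-domain voxels become background (0). The output grid is exactly
#' the target grid.
#'
#' @param labels A [LabelMap-class] (the moving labels).
#' @param transform A [SpatialTransform-class] whose displacement field, if
#'   any, is defined on the target grid.
#' @param target A list with \code{dim}, \code{spacing}, \code{origin}
#'   describing the target grid, or an object with those accessors
#'   ([ImageVolume-class] / [LabelMap-class]).
#' @return A [LabelMap-class] on the target grid.
#' @export
warpLabels <- function(labels, transform, target) {
  tgeom <- if (is.list(target)) target else .geomOf(target)
  .checkFieldGrid(transform, tgeom)
  out <- .warpRaw(labels@data, .geomOf(labels), tgeom,
                  transform@translation, transform@displacementField,
                  nearest = TRUE, pad = 0)
  labelMap(out, spacing = tgeom$spacing, origin = tgeom$origin,
           labelValues = labels@labelValues)
}

#' Warp an intensity image onto a target grid
#'
#' Trilinear interpolation; out-of-domain voxels take \code{pad}.
#'
#' @inheritParams warpLabels
#' @param image An [ImageVolume-class] (the moving image).
#' @param pad Padding intensity for out-of-domain voxels.
#' @return An [ImageVolume-class] on the target grid.
#' @export
warpImage <- function(image, transform, target, pad = 0) {
  tgeom <- if (is.list(target)) target else .geomOf(target)
  .checkFieldGrid(transform, tgeom)
  out <- .warpRaw(image@data, .geomOf(image), tgeom,
                  transform@translation, transform@displacementField,
                  nearest = FALSE, pad = pad)
  imageVolume(out, spacing = tgeom$spacing, origin = tgeom$origin)
}
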