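#' @include core-model.R
NULL

#' Binary mask of one class
#'
#' @param labels A [LabelMap-class].
#' @param classLabel Integer class code; must be one of the map's declared
#'   label values.
#' @return Logical 3D array, \code{TRUE} exactly where the label equals
#'   \code{classLabel}.
#' @export
classMask <- function(labels, classLabel) {
  if (!classLabel %in% labels@labelValues)
    stop(sprintf("class label %d is not declared for this LabelMap",
                 as.integer(classLabel)))
  labels@data == as.integer(classLabel)
}

#' Whole-heart mask: union of all atomic classes
#'
#' @param labels A [LabelMap-class].
#' @param spec A [ClassSpec-class].
#' @return Logical 3D array, \code{TRUE} where the voxel carries any atomic
#'   (non-background) label.
#' @export
wholeHeartMask <- function(labels, spec = defaultClassSpec()) {
  array(labels@data %in% as.integer(spec@atomicClasses), dim(labels@data))
}

#' Dice similarity coefficient between two binary masks
#'
#' \code{DSC = 2|A intersect B| / (|A| + |B|)}. Two empty masks compare as a
#' defined 1.0 carrying the attribute \code{emptyEmpty = TRUE}; an empty
#' mask against a non-empty one scores 0, so a wholly missing class in a
#' failed segmentation registers as failure.
#'
#' @param a,b Logical 3D arrays on one grid.
#' @return Numeric scalar in \[0, 1\].
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks are defined on incompatible grids")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0L)
    return(structure(1.0, emptyEmpty = TRUE))
  2 * sum(a & b) / (na + nb)
}

#' Surface voxels of a binary mask
#'
#' The surface is the set of foreground voxels with at least one
#' 6-connected (face) neighbour that is background or outside the grid.
#'
#' @param mask Logical 3D array.
#' @return Integer matrix (n x 3) of 1-based voxel indices; zero rows for an
#'   empty mask.
#' @export
surfaceVoxels <- function(mask) {
  d <- dim(mask)
  if (!any(mask)) return(matrix(integer(), 0L, 3L))
  interior <- mask
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      shifted <- array(FALSE, d)
      n <- d[ax]
      if (n == 1L) {
        # any voxel on a singleton axis touches out-of-bounds
        shifted[] <- FALSE
      } else if (ax == 1L) {
        if (dir == 1L) shifted[1:(n - 1), , ] <- mask[2:n, , ]
        else shifted[2:n, , ] <- mask[1:(n - 1), , ]
      } else if (ax == 2L) {
        if (dir == 1L) shifted[, 1:(n - 1), ] <- mask[, 2:n, ]
        else shifted[, 2:n, ] <- mask[, 1:(n - 1), ]
      } else {
        if (dir == 1L) shifted[, , 1:(n - 1)] <- mask[, , 2:n]
        else shifted[, , 2:n] <- mask[, , 1:(n - 1)]
      }
      interior <- interior & shifted
    }
  }
  which(mask & !interior, arr.ind = TRUE, useNames = FALSE)
}

.surfacePoints <- function(mask, spacing) {
  idx <- surfaceVoxels(mask)
  # physical voxel-centre coordinates; any common origin cancels in distances
  sweep(idx - 1L, 2L, spacing, `*`)
}

#' Directed surface distances from mask A to mask B
#'
#' For every surface voxel of \code{a}, the minimum physical-space Euclidean
#' distance (mm) from its centre to any surface-voxel centre of \code{b},
#' with anisotropic spacing applied per axis. Not symmetric.
#'
#' @param a,b Logical 3D arrays on one grid.
#' @param spacing Voxel size in mm per axis.
#' @return Numeric vector of per-point distances, or \code{NULL} (the
#'   undefined signal) when either mask is empty.
#' @export
directedSurfaceDistances <- function(a, b, spacing) {
  if (!identical(dim(a), dim(b)))
    stop("masks are defined on incompatible grids")
  if (!any(a) || !any(b)) return(NULL)
  A <- .surfacePoints(a, spacing)
  B <- .surfacePoints(b, spacing)
  cpp_directed_min_dists(A, B)
}

#' Symmetric surface-distance statistics (MSD, RMSD, HD)
#'
#' Pools the directed distances A to B with those from B to A and reports
#' the mean (MSD), root mean square (RMSD) and maximum (HD) of the pooled
#' list, all in mm. Undefined (\code{NA}) when either mask is empty.
#'
#' @inheritParams directedSurfaceDistances
#' @return Named numeric vector \code{c(msd, rmsd, hd)}.
#' @export
symmetricDistanceStats <- function(a, b, spacing) {
  if (!identical(dim(a), dim(b)))
    stop("masks are defined on incompatible grids")
  dab <- directedSurfaceDistances(a, b, spacing)
  if (is.null(dab))
    return(c(msd = NA_real_, rmsd = NA_real_, hd = NA_real_))
  dba <- directedSurfaceDistances(b, a, spacing)
  pooled <- c(dab, dba)
  c(msd = mean(pooled), rmsd = sqrt(mean(pooled^2)), hd = max(pooled))
}

.emptyClassMetrics <- function(classes) {
  data.frame(class = c(classes, "AV", "WH"), dsc = NA_real_,
             msd = NA_real_, rmsd = NA_real_, hd = NA_real_,
             stringsAsFactors = FALSE)
}

#' Evaluate all quality metrics between two label maps
#'
#' Computes DSC, MSD, RMSD and HD for every atomic class, for the merged
#' whole-heart (WH) mask, and the unweighted class average (AV) of the
#' defined per-class values. DSC of a class empty in exactly one map is 0;
#' its surface distances are undefined (\code{NA}). A class empty in both
#' maps has DSC 1 (the flagged empty-vs-empty convention) and undefined
#' distances.
#'
#' @param segA,segB [LabelMap-class] objects on one grid.
#' @param spec A [ClassSpec-class].
#' @return ClassMetrics data frame with columns
#'   \code{class, dsc, msd, rmsd, hd} and rows for each atomic class plus
#'   \code{AV} and \code{WH}.
#' @export
evaluatePair <- function(segA, segB, spec = defaultClassSpec()) {
  .stopIfGridMismatch(segA, segB)
  sp <- segA@spacing
  classes <- names(spec@atomicClasses)
  out <- .emptyClassMetrics(classes)
  for (nm in classes) {
    code <- spec@atomicClasses[[nm]]
    ma <- segA@data == code
    mb <- segB@data == code
    i <- which(out$class == nm)
    out$dsc[i] <- as.numeric(diceCoefficient(ma, mb))
    st <- symmetricDistanceStats(ma, mb, sp)
    out$msd[i] <- st[["msd"]]
    out$rmsd[i] <- st[["rmsd"]]
    out$hd[i] <- st[["hd"]]
  }
  wa <- array(segA@data %in% as.integer(spec@atomicClasses), dim(segA@data))
  wb <- array(segB@data %in% as.integer(spec@atomicClasses), dim(segB@data))
  iw <- which(out$class == "WH")
  out$dsc[iw] <- as.numeric(diceCoefficient(wa, wb))
  st <- symmetricDistanceStats(wa, wb, sp)
  out$msd[iw] <- st[["msd"]]
  out$rmsd[iw] <- st[["rmsd"]]
  out$hd[iw] <- st[["hd"]]
  ia <- which(out$class == "AV")
  per <- out[out$class %in% classes, ]
  for (m in c("dsc", "msd", "rmsd", "hd")) {
    v <- per[[m]][!is.na(per[[m]])]
    out[[m]][ia] <- if (length(v)) mean(v) else NA_real_
  }
  out
}
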