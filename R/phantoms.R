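#' @include metrics.R
NULL

#' Specification of a synthetic short-axis cardiac phantom
#'
#' Describes the cardiac-like three-class geometry generated per subject: a
#' circular LV cavity disc, a surrounding LV myocardium annulus, and a
#' crescent-shaped RV cavity abutting the myocardium, with radii tapering
#' toward the apical slices. The grid emulates stack-of-2D short-axis CMR
#' with anisotropic voxels (default 64x64x10 voxels at 1.8x1.8x8.0 mm).
#' Per-subject jitter perturbs the heart position and sizes, intensities
#' are class means plus Gaussian noise and a low-frequency bias field, and
#' everything is deterministic for a fixed seed.
#'
#' @param shape Voxel counts per axis.
#' @param spacing Voxel size in mm per axis.
#' @param lvCenterOffset In-plane offset (mm) of the LV centre from the
#'   grid centre (positive x leaves room for the RV on the other side).
#' @param lvCavityRadius Basal LV cavity radius, mm.
#' @param myoThickness Basal myocardium thickness, mm.
#' @param rvOffset In-plane offset (mm) of the RV centre from the LV centre.
#' @param rvRadius Basal RV disc radius, mm (the crescent is the part of
#'   this disc outside the LV epicardial footprint).
#' @param apexTaper Fractional radius reduction from base to apex.
#' @param centerJitter,radiusJitter Per-subject jitter: centre shift range
#'   (mm) and fractional radius/thickness perturbation.
#' @param intensityMeans Named intensities for background/LVC/LVM/RVC.
#' @param noiseSd Gaussian intensity noise SD.
#' @param biasAmplitude Amplitude of the smooth intensity bias field.
#' @param seed Integer seed.
#' @return A list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(shape = c(64L, 64L, 10L),
                        spacing = c(1.8, 1.8, 8.0),
                        lvCenterOffset = c(8, 0),
                        lvCavityRadius = 20, myoThickness = 8,
                        rvOffset = c(-34, 2), rvRadius = 16,
                        apexTaper = 0.4,
                        centerJitter = 4, radiusJitter = 0.12,
                        intensityMeans = c(background = 40, LVC = 190,
                                           LVM = 100, RVC = 170),
                        noiseSd = 12, biasAmplitude = 20, seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               lvCenterOffset = lvCenterOffset,
               lvCavityRadius = lvCavityRadius, myoThickness = myoThickness,
               rvOffset = rvOffset, rvRadius = rvRadius,
               apexTaper = apexTaper, centerJitter = centerJitter,
               radiusJitter = radiusJitter, intensityMeans = intensityMeans,
               noiseSd = noiseSd, biasAmplitude = biasAmplitude,
               seed = as.integer(seed))
  stopifnot(all(spec$shape >= 1L), all(spec$spacing > 0),
            spec$lvCavityRadius > 0, spec$myoThickness > 0,
            spec$rvRadius > 0, spec$apexTaper >= 0, spec$apexTaper < 1,
            spec$noiseSd >= 0, spec$biasAmplitude >= 0)
  class(spec) <- "PhantomSpec"
  spec
}

#' Generate one synthetic cardiac phantom atlas
#'
#' Builds the per-slice disc / annulus / crescent geometry described by the
#' spec, applies per-subject jitter, and synthesises the intensity image as
#' class-mean intensities plus Gaussian noise and a low-frequency bias
#' field. Deterministic for a fixed seed. Errors if the jittered structures
#' would leave the grid.
#'
#' @param spec A [phantomSpec()] list.
#' @param id Atlas identifier.
#' @return An [Atlas-class].
#' @export
generatePhantom <- function(spec = phantomSpec(), id = "phantom_0001") {
  set.seed(spec$seed)
  d <- spec$shape
  sp <- spec$spacing
  extent <- (d - 1L) * sp
  gridCenter <- extent[1:2] / 2

  jc <- stats::runif(2, -spec$centerJitter, spec$centerJitter)
  jr <- 1 + stats::runif(3, -spec$radiusJitter, spec$radiusJitter)
  lvC <- gridCenter + spec$lvCenterOffset + jc
  rC <- spec$lvCavityRadius * jr[1]
  th <- spec$myoThickness * jr[2]
  rvR <- spec$rvRadius * jr[3]
  rvC <- lvC + spec$rvOffset

  # geometric feasibility: basal structures must stay inside the grid
  maxR <- rC + th
  if (lvC[1] - maxR < 0 || lvC[1] + maxR > extent[1] ||
      lvC[2] - maxR < 0 || lvC[2] + maxR > extent[2] ||
      rvC[1] - rvR < 0 || rvC[1] + rvR > extent[1] ||
      rvC[2] - rvR < 0 || rvC[2] + rvR > extent[2])
    stop("phantom structures exceed the grid for this spec/seed")

  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  dxLV <- outer(x - lvC[1], rep(1, d[2]))
  dyLV <- outer(rep(1, d[1]), y - lvC[2])
  rLV <- sqrt(dxLV^2 + dyLV^2)
  dxRV <- outer(x - rvC[1], rep(1, d[2]))
  dyRV <- outer(rep(1, d[1]), y - rvC[2])
  rRV <- sqrt(dxRV^2 + dyRV^2)

  labels <- array(0L, d)
  nz <- d[3]
  for (k in seq_len(nz)) {
    # slice nz is the base (scale 1), slice 1 the apex
    scale <- 1 - spec$apexTaper * (nz - k) / max(nz - 1L, 1L)
    slice <- matrix(0L, d[1], d[2])
    slice[rRV <= rvR * scale & rLV > (rC + th) * scale] <- 3L
    slice[rLV <= (rC + th) * scale] <- 2L
    slice[rLV <= rC * scale] <- 1L
    labels[, , k] <- slice
  }

  mu <- spec$intensityMeans
  img <- array(mu[["background"]], d)
  img[labels == 1L] <- mu[["LVC"]]
  img[labels == 2L] <- mu[["LVM"]]
  img[labels == 3L] <- mu[["RVC"]]
  if (spec$biasAmplitude > 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    bias2d <- spec$biasAmplitude *
      outer(sin(2 * pi * x / max(extent[1], 1) + ph[1]),
            sin(2 * pi * y / max(extent[2], 1) + ph[2]))
    img <- img + array(bias2d, d)
  }
  if (spec$noiseSd > 0)
    img <- img + array(stats::rnorm(prod(d), 0, spec$noiseSd), d)

  atlas(id,
        imageVolume(img, spacing = sp),
        labelMap(labels, spacing = sp))
}

.deriveSeed <- function(seed, offset) as.integer((seed + offset) %% 2147483647)

#' Generate a cohort of phantoms with independent per-subject jitter
#'
#' @param n Number of subjects.
#' @param spec A [phantomSpec()]; its seed is the cohort seed from which
#'   per-subject seeds are derived.
#' @param seed Optional cohort seed overriding \code{spec$seed}.
#' @param idPrefix Prefix for the generated ids (\code{"phantom"} gives
#'   \code{phantom_0001} ...).
#' @return List of [Atlas-class] objects.
#' @export
generateCohort <- function(n, spec = phantomSpec(), seed = spec$seed,
                           idPrefix = "phantom") {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- .deriveSeed(seed, 1000L + i)
    generatePhantom(s, id = sprintf("%s_%04d", idPrefix, i))
  })
}

#' Specification of a segmentation degradation
#'
#' @param operator One of \code{"boundary_erode"}, \code{"boundary_dilate"},
#'   \code{"slice_dropout"}, \code{"patch_relabel"}, \code{"translate"},
#'   \code{"class_delete"}.
#' @param severity Non-negative operator-specific severity (voxels of
#'   erosion/dilation/shift, number of slices, patches or classes);
#'   severity 0 is the identity for every operator.
#' @param seed Integer seed for the operator's random choices.
#' @return A list of class \code{"DegradationSpec"}.
#' @export
degradationSpec <- function(operator, severity, seed = 1L) {
  operator <- match.arg(operator,
                        c("boundary_erode", "boundary_dilate",
                          "slice_dropout", "patch_relabel", "translate",
                          "class_delete"))
  stopifnot(severity >= 0)
  structure(list(operator = operator, severity = severity,
                 seed = as.integer(seed)),
            class = "DegradationSpec")
}

.erodeMask2d <- function(m) {
  # 4-neighbour in-plane erosion of a logical matrix
  d <- dim(m)
  out <- m
  out[1, ] <- FALSE; out[d[1], ] <- FALSE
  out[, 1] <- FALSE; out[, d[2]] <- FALSE
  sh <- function(di, dj) {
    s <- matrix(FALSE, d[1], d[2])
    ii <- (1 + max(0, di)):(d[1] + min(0, di))
    jj <- (1 + max(0, dj)):(d[2] + min(0, dj))
    s[ii, jj] <- m[ii - di, jj - dj]
    s
  }
  out & sh(1, 0) & sh(-1, 0) & sh(0, 1) & sh(0, -1)
}

.dilateMask2d <- function(m) {
  d <- dim(m)
  sh <- function(di, dj) {
    s <- matrix(FALSE, d[1], d[2])
    ii <- (1 + max(0, di)):(d[1] + min(0, di))
    jj <- (1 + max(0, dj)):(d[2] + min(0, dj))
    s[ii, jj] <- m[ii - di, jj - dj]
    s
  }
  m | sh(1, 0) | sh(-1, 0) | sh(0, 1) | sh(0, -1)
}

#' Apply a controlled degradation to a label map
#'
#' Emulates automatic segmentations of varying quality: in-plane boundary
#' erosion or dilation per class, dropping whole slices, relabelling random
#' patches, rigid in-plane translation of the labels, or deleting entire
#' classes. Severity 0 returns a voxel-identical copy; increasing severity
#' reduces agreement with the input (whole-heart DSC non-increasing in
#' expectation). Output labels always stay within the input label set.
#'
#' @param labels A [LabelMap-class].
#' @param spec A [degradationSpec()].
#' @return A degraded [LabelMap-class] on the same grid.
#' @export
degradeLabelmap <- function(labels, spec) {
  stopifnot(inherits(spec, "DegradationSpec"))
  set.seed(spec$seed)
  dat <- labels@data
  d <- dim(dat)
  sev <- spec$severity
  if (sev == 0) return(labels)
  atomic <- setdiff(sort(unique(as.integer(labels@labelValues))), 0L)

  if (spec$operator == "boundary_erode") {
    for (k in seq_len(d[3])) {
      slice <- dat[, , k]
      for (cl in atomic) {
        m <- slice == cl
        for (it in seq_len(round(sev))) m <- .erodeMask2d(m)
        slice[slice == cl & !m] <- 0L
      }
      dat[, , k] <- slice
    }
  } else if (spec$operator == "boundary_dilate") {
    for (k in seq_len(d[3])) {
      slice <- dat[, , k]
      for (cl in atomic) {
        m <- slice == cl
        for (it in seq_len(round(sev))) m <- .dilateMask2d(m)
        slice[m & slice == 0L] <- cl
      }
      dat[, , k] <- slice
    }
  } else if (spec$operator == "slice_dropout") {
    k <- min(round(sev), d[3])
    drop <- sample(seq_len(d[3]), k)
    dat[, , drop] <- 0L
  } else if (spec$operator == "patch_relabel") {
    fg <- which(dat != 0L, arr.ind = TRUE)
    if (nrow(fg) > 0L) {
      sx <- labels@spacing
      for (p in seq_len(round(sev))) {
        ctr <- fg[sample(nrow(fg), 1L), ]
        radius <- stats::runif(1, 4, 9) # mm
        newLab <- sample(c(0L, atomic), 1L)
        lo <- pmax(1L, ctr - ceiling(radius / sx))
        hi <- pmin(d, ctr + ceiling(radius / sx))
        for (k in lo[3]:hi[3]) for (j in lo[2]:hi[2]) for (i in lo[1]:hi[1]) {
          dd <- sum((( c(i, j, k) - ctr) * sx)^2)
          if (dd <= radius^2) dat[i, j, k] <- newLab
        }
      }
    }
  } else if (spec$operator == "translate") {
    ang <- sample(0:7, 1L) * pi / 4
    shift <- round(sev * c(cos(ang), sin(ang)))
    out <- array(0L, d)
    ii <- seq_len(d[1]); jj <- seq_len(d[2])
    si <- ii - shift[1]; sj <- jj - shift[2]
    keepI <- si >= 1 & si <= d[1]
    keepJ <- sj >= 1 & sj <= d[2]
    out[ii[keepI], jj[keepJ], ] <- dat[si[keepI], sj[keepJ], ]
    dat <- out
  } else if (spec$operator == "class_delete") {
    k <- min(round(sev), length(atomic))
    del <- sample(atomic, k)
    dat[dat %in% del] <- 0L
  }
  labelMap(dat, spacing = labels@spacing, origin = labels@origin,
           labelValues = labels@labelValues)
}

.defaultSeverityMenu <- function() {
  # (operator, severity, intended category at the WH DSC 0.7 boundary);
  # severities placed from measured degradation ladders on default phantoms
  rbind(
    data.frame(operator = "boundary_erode", severity = c(0, 1, 2, 3, 4, 5),
               intended = c("good", "good", "poor", "poor", "poor", "poor")),
    data.frame(operator = "boundary_dilate", severity = c(0, 1, 2, 7, 10),
               intended = c("good", "good", "good", "poor", "poor")),
    data.frame(operator = "slice_dropout", severity = c(1, 2, 6, 8),
               intended = c("good", "good", "poor", "poor")),
    data.frame(operator = "patch_relabel", severity = c(1, 3, 6),
               intended = c("good", "good", "good")),
    data.frame(operator = "translate", severity = c(2, 3, 8, 12, 16),
               intended = c("good", "good", "poor", "poor", "poor"))
  )
}

#' Build a reference cohort plus degraded test cases for validation
#'
#' Generates a reference cohort and a disjoint test cohort of phantoms;
#' each test case's predicted segmentation is a degraded copy of its ground
#' truth, with operators and severities drawn from a menu spanning the
#' quality spectrum. The builder measures the real whole-heart DSC of every
#' degraded segmentation and escalates or relaxes the severity (up to three
#' attempts) when a draw misses its intended good/poor side of the
#' threshold, so the realised real-DSC distribution covers both sides of
#' 0.7 and reaches down to severely failed segmentations. Fully
#' reproducible for a fixed seed.
#'
#' @param nRefs,nTests Cohort sizes (each at least 1).
#' @param spec A [phantomSpec()] shared by both cohorts.
#' @param seed Master seed; cohort, subject and degradation seeds derive
#'   from it.
#' @param goodFraction Fraction of test cases aimed at the good side of the
#'   DSC 0.7 boundary.
#' @param thresholds A [QualityThresholds-class] used only for the coverage
#'   calibration.
#' @return List with \code{references} (list of [Atlas-class]),
#'   \code{tests} (list of [RcaTestCase-class] with ground truth) and
#'   \code{manifest} (data frame case_id, operator, severity, seed,
#'   real_wh_dsc).
#' @export
buildValidationSuite <- function(nRefs, nTests, spec = phantomSpec(),
                                 seed = 1L, goodFraction = 0.6,
                                 thresholds = qualityThresholds()) {
  stopifnot(nRefs >= 1L, nTests >= 1L)
  references <- generateCohort(nRefs, spec, seed = .deriveSeed(seed, 0L),
                               idPrefix = "ref")
  gtAtlases <- generateCohort(nTests, spec, seed = .deriveSeed(seed, 500000L),
                              idPrefix = "test")
  menu <- .defaultSeverityMenu()
  set.seed(.deriveSeed(seed, 900000L))
  intended <- ifelse(stats::runif(nTests) < goodFraction, "good", "poor")
  tests <- vector("list", nTests)
  manifest <- data.frame()
  for (i in seq_len(nTests)) {
    gt <- gtAtlases[[i]]
    rows <- menu[menu$intended == intended[i], ]
    pick <- rows[sample(nrow(rows), 1L), ]
    op <- pick$operator
    sev <- pick$severity
    degSeed <- .deriveSeed(seed, 900000L + 17L * i)
    for (attempt in 1:3) {
      dspec <- degradationSpec(op, sev, seed = degSeed + attempt)
      degraded <- degradeLabelmap(gt@labels, dspec)
      if (!any(degraded@data != 0L)) {
        sev <- max(sev - 1, 0)
        dspec <- degradationSpec(op, sev, seed = degSeed + attempt)
        degraded <- degradeLabelmap(gt@labels, dspec)
      }
      realDsc <- diceCoefficient(wholeHeartMask(degraded),
                                 wholeHeartMask(gt@labels))
      lab <- classifyValue(realDsc, "dsc", thresholds)
      if (lab == intended[i] || attempt == 3L) break
      opRows <- menu[menu$operator == op, ]
      sev <- if (intended[i] == "poor") {
        cand <- opRows$severity[opRows$severity > sev]
        if (length(cand)) min(cand) else sev + 1
      } else {
        cand <- opRows$severity[opRows$severity < sev]
        if (length(cand)) max(cand) else max(sev - 1, 0)
      }
    }
    tests[[i]] <- rcaTestCase(gt@id, gt@image, degraded,
                              gtLabels = gt@labels)
    manifest <- rbind(manifest,
                      data.frame(case_id = gt@id, role = "test",
                                 operator = op, severity = sev,
                                 seed = dspec$seed,
                                 real_wh_dsc = as.numeric(realDsc),
                                 stringsAsFactors = FALSE))
  }
  refManifest <- data.frame(
    case_id = vapply(references, function(a) a@id, character(1)),
    role = "reference", operator = NA_character_, severity = NA_real_,
    seed = NA_integer_, real_wh_dsc = NA_real_, stringsAsFactors = FALSE)
  list(references = references, tests = tests,
       manifest = rbind(refManifest, manifest))
}
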