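test_that("class and whole-heart masks match brute-force counting", {
  lab <- tinyLabelMap()
  for (cl in 1:3)
    expect_equal(sum(classMask(lab, cl)), sum(voxelData(lab) == cl))
  expect_error(classMask(lab, 9L), "not declared")
  wh <- wholeHeartMask(lab)
  expect_identical(wh, classMask(lab, 1L) | classMask(lab, 2L) |
                     classMask(lab, 3L))
  empty <- labelMap(array(0L, c(4, 4, 2)))
  expect_false(any(wholeHeartMask(empty)))
})

test_that("dice handles identity, disjoint, shifted and empty masks", {
  d <- c(6L, 6L, 6L)
  cube <- array(FALSE, d)
  cube[2:3, 2:3, 2:3] <- TRUE
  expect_equal(diceCoefficient(cube, cube), 1.0)
  shifted <- array(FALSE, d)
  shifted[3:4, 2:3, 2:3] <- TRUE
  expect_equal(diceCoefficient(cube, shifted), 0.5)
  disjoint <- array(FALSE, d)
  disjoint[5:6, 5:6, 5:6] <- TRUE
  expect_equal(diceCoefficient(cube, disjoint), 0.0)
  none <- array(FALSE, d)
  ee <- diceCoefficient(none, none)
  expect_equal(as.numeric(ee), 1.0)
  expect_true(attr(ee, "emptyEmpty"))
  expect_equal(diceCoefficient(none, cube), 0.0)
  expect_error(diceCoefficient(cube, array(FALSE, c(5, 6, 6))),
               "incompatible")
})

test_that("surface voxels are the 6-connected boundary", {
  d <- c(7L, 7L, 7L)
  single <- array(FALSE, d)
  single[4, 4, 4] <- TRUE
  expect_equal(surfaceVoxels(single), matrix(c(4L, 4L, 4L), 1))
  cube <- array(FALSE, d)
  cube[3:5, 3:5, 3:5] <- TRUE
  expect_equal(nrow(surfaceVoxels(cube)), 26L)  # 27 voxels - 1 interior
  plate <- array(FALSE, d)
  plate[2:6, 2:6, 4] <- TRUE
  expect_equal(nrow(surfaceVoxels(plate)), 25L) # every voxel touches bg
  expect_equal(nrow(surfaceVoxels(array(FALSE, d))), 0L)
})

test_that("directed distances respect anisotropic spacing", {
  d <- c(8L, 8L, 8L)
  a <- array(FALSE, d); a[3, 4, 4] <- TRUE
  b <- array(FALSE, d); b[5, 4, 4] <- TRUE
  expect_equal(directedSurfaceDistances(a, b, c(1.25, 1.25, 2.0)), 2.5)
  expect_equal(directedSurfaceDistances(a, a, c(1.25, 1.25, 2.0)), 0)
  expect_null(directedSurfaceDistances(a, array(FALSE, d), c(1, 1, 1)))

  # two parallel 3x3x1 plates two slices apart at sz = 2 mm
  p1 <- array(FALSE, d); p1[3:5, 3:5, 2] <- TRUE
  p2 <- array(FALSE, d); p2[3:5, 3:5, 4] <- TRUE
  expect_equal(directedSurfaceDistances(p1, p2, c(1, 1, 2)), rep(4, 9))
})

test_that("symmetric statistics pool both directions", {
  d <- c(8L, 8L, 8L)
  a <- array(FALSE, d); a[3, 4, 4] <- TRUE
  b <- array(FALSE, d); b[5, 4, 4] <- TRUE
  st <- symmetricDistanceStats(a, b, c(1.25, 1.25, 2.0))
  expect_equal(st, c(msd = 2.5, rmsd = 2.5, hd = 2.5))
  expect_equal(symmetricDistanceStats(a, a, c(1, 1, 1)),
               c(msd = 0, rmsd = 0, hd = 0))
  st <- symmetricDistanceStats(a, array(FALSE, d), c(1, 1, 1))
  expect_true(all(is.na(st)))
})

test_that("metrics agree with the brute-force oracle on random masks", {
  set.seed(7)
  for (trial in 1:30) {
    d <- sample(5:12, 3, replace = TRUE)
    sp <- runif(3, 0.8, 4)
    a <- randomBlobMask(d)
    b <- randomBlobMask(d)
    expect_equal(as.numeric(diceCoefficient(a, b)), bfDice(a, b),
                 tolerance = 1e-12)
    st <- symmetricDistanceStats(a, b, sp)
    bf <- bfDistanceStats(a, b, sp)
    if (any(is.na(bf))) {
      expect_true(all(is.na(st)))
      next
    }
    expect_equal(st, bf, tolerance = 1e-9)
    # symmetry and ordering
    expect_equal(st, symmetricDistanceStats(b, a, sp), tolerance = 1e-12)
    expect_true(st[["msd"]] <= st[["rmsd"]] + 1e-12)
    expect_true(st[["rmsd"]] <= st[["hd"]] + 1e-12)
  }
})

test_that("metrics are invariant to joint integer translation", {
  set.seed(11)
  d <- c(12L, 12L, 8L)
  a <- array(FALSE, d); a[3:5, 4:6, 2:4] <- TRUE
  b <- array(FALSE, d); b[4:7, 3:5, 3:5] <- TRUE
  sp <- c(1.8, 1.8, 8)
  shift <- c(2L, 1L, 1L)
  tr <- function(m) {
    out <- array(FALSE, d)
    out[(1 + shift[1]):d[1], (1 + shift[2]):d[2], (1 + shift[3]):d[3]] <-
      m[1:(d[1] - shift[1]), 1:(d[2] - shift[2]), 1:(d[3] - shift[3])]
    out
  }
  expect_equal(diceCoefficient(a, b), diceCoefficient(tr(a), tr(b)))
  expect_equal(symmetricDistanceStats(a, b, sp),
               symmetricDistanceStats(tr(a), tr(b), sp), tolerance = 1e-12)
})

test_that("evaluatePair covers per-class, AV and WH conventions", {
  lab <- tinyLabelMap()
  same <- evaluatePair(lab, lab)
  expect_equal(same$dsc, rep(1, 5))
  expect_equal(same$msd, rep(0, 5))
  expect_equal(same$hd, rep(0, 5))

  # LVM relabelled to background in one map
  dat <- voxelData(lab)
  dat[dat == 2L] <- 0L
  noLvm <- labelMap(dat, spacing = spacing(lab))
  m <- evaluatePair(lab, noLvm)
  expect_equal(m$dsc[m$class == "LVM"], 0.0)
  expect_true(all(is.na(m[m$class == "LVM", c("msd", "rmsd", "hd")])))
  expect_lt(m$dsc[m$class == "WH"], 1)
  # AV is the mean over defined per-class values
  per <- m[m$class %in% c("LVC", "LVM", "RVC"), ]
  expect_equal(m$dsc[m$class == "AV"], mean(per$dsc), tolerance = 1e-12)
  expect_equal(m$msd[m$class == "AV"], mean(per$msd, na.rm = TRUE),
               tolerance = 1e-12)

  # WH merged-mask DSC differs from (and here exceeds) the class average:
  # cross-class confusions stay correct in the merged binary task
  confDat <- voxelData(lab)
  confDat[confDat == 1L] <- 2L
  confDat[confDat == 3L] <- 1L
  conf <- labelMap(confDat, spacing = spacing(lab))
  cm <- evaluatePair(lab, conf)
  expect_equal(cm$dsc[cm$class == "WH"], 1.0)
  expect_gt(cm$dsc[cm$class == "WH"], cm$dsc[cm$class == "AV"])

  expect_error(evaluatePair(lab, tinyLabelMap(spacing = c(2, 1, 2))),
               "incompatible")
})
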