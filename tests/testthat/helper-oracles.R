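# Independent brute-force oracles for the overlap and surface-distance
# metrics, plus small fixture builders. Everything here is written directly
# from the definitions (loops and all-pairs enumeration) and shares no code
# with the package's compiled implementation.

bfDice <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

bfSurface <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(idx)
  keep <- logical(nrow(idx))
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(idx))) {
    for (s in seq_len(6)) {
      p <- idx[r, ] + nbr[s, ]
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        keep[r] <- TRUE
        break
      }
    }
  }
  idx[keep, , drop = FALSE]
}

bfDirectedDists <- function(a, b, spacing) {
  A <- bfSurface(a)
  B <- bfSurface(b)
  if (nrow(A) == 0L || nrow(B) == 0L) return(NULL)
  Ap <- sweep(A - 1, 2, spacing, `*`)
  Bp <- sweep(B - 1, 2, spacing, `*`)
  vapply(seq_len(nrow(Ap)), function(i) {
    sqrt(min(colSums((t(Bp) - Ap[i, ])^2)))
  }, numeric(1))
}

bfDistanceStats <- function(a, b, spacing) {
  dab <- bfDirectedDists(a, b, spacing)
  dba <- bfDirectedDists(b, a, spacing)
  if (is.null(dab) || is.null(dba))
    return(c(msd = NA_real_, rmsd = NA_real_, hd = NA_real_))
  pooled <- c(dab, dba)
  c(msd = mean(pooled), rmsd = sqrt(mean(pooled^2)), hd = max(pooled))
}

# a random blob mask: union of 1-3 random ellipsoids (structured enough to
# have a proper surface, unlike iid voxel noise)
randomBlobMask <- function(d, nBlobs = sample(1:3, 1)) {
  m <- array(FALSE, d)
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  for (b in seq_len(nBlobs)) {
    c0 <- runif(3, 2, d - 1)
    r0 <- runif(3, 1, pmax(2, d / 2.5))
    dist2 <- outer(outer(((x - c0[1]) / r0[1])^2,
                         ((y - c0[2]) / r0[2])^2, `+`),
                   ((z - c0[3]) / r0[3])^2, `+`)
    m <- m | (dist2 <= 1)
  }
  m
}

# small three-class label map built from concentric boxes, on an arbitrary
# grid; deterministic given the arguments
tinyLabelMap <- function(d = c(8L, 8L, 4L), spacing = c(1, 1, 2),
                         origin = c(0, 0, 0)) {
  lab <- array(0L, d)
  lab[3:6, 3:6, 2:3] <- 2L
  lab[4:5, 4:5, 2:3] <- 1L
  lab[2, 3:6, 2:3] <- 3L
  labelMap(lab, spacing = spacing, origin = origin)
}

tinyAtlas <- function(id = "tiny", d = c(8L, 8L, 4L), spacing = c(1, 1, 2)) {
  lab <- tinyLabelMap(d, spacing)
  img <- array(10, d)
  img[voxelData(lab) == 1L] <- 100
  img[voxelData(lab) == 2L] <- 60
  img[voxelData(lab) == 3L] <- 90
  atlas(id, imageVolume(img, spacing = spacing), lab)
}

# fast shared phantom pair for registration tests
smallPhantomSpec <- function(seed = 1L)
  phantomSpec(shape = c(32L, 32L, 6L), spacing = c(3.6, 3.6, 10),
              lvCavityRadius = 18, myoThickness = 8, rvRadius = 14,
              rvOffset = c(-31, 2), centerJitter = 3, seed = seed)
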