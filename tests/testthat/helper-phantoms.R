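# Shared fixtures: small phantoms built in code at test time.

# noiseless cylinder phantom on a small grid; cheap enough to rebuild
smallCylinderPhantom <- function(radius = 8, length = 80, spacing = 1,
                                 tilt = 0, noise = 0, seed = 3L,
                                 nFragments = 0L, streaks = FALSE,
                                 block = c(70, 70, 110)) {
  generatePhantom(phantomSpec(
    blockShapeMm = block, voxelSpacingMm = spacing,
    cavityFamily = "cylinder",
    cavityParams = list(radius_mm = radius, length_mm = length,
                        tilt_deg = tilt),
    nFragments = nFragments, streakArtifacts = streaks,
    noiseSdHu = noise, seed = seed))
}

# a digitized solid of revolution as a standalone mask (no phantom machinery):
# independent construction used as oracle input for morphometry tests
digitizedBall <- function(radius = 10, spacing = 0.5, pad = 3) {
  n <- as.integer(ceiling(2 * (radius + pad) / spacing))
  cc <- (seq_len(n) - 0.5) * spacing
  ctr <- (n * spacing) / 2
  d2 <- outer(outer((cc - ctr)^2, (cc - ctr)^2, `+`), (cc - ctr)^2, `+`)
  BinaryMask(array(d2 <= radius^2, dim = c(n, n, n)),
             spacing = rep(spacing, 3))
}

digitizedCylinder <- function(radius = 8, length = 100, spacing = 1,
                              pad = 4, axis = 3) {
  nxy <- as.integer(ceiling(2 * (radius + pad) / spacing))
  nz <- as.integer(ceiling((length + 2 * pad) / spacing))
  cc <- (seq_len(nxy) - 0.5) * spacing
  ctr <- (nxy * spacing) / 2
  zc <- (seq_len(nz) - 0.5) * spacing
  inxy <- outer((cc - ctr)^2, (cc - ctr)^2, `+`) <= radius^2
  inz <- zc >= pad & zc <= pad + length
  arr <- array(FALSE, c(nxy, nxy, nz))
  for (k in which(inz)) arr[, , k] <- inxy
  m <- BinaryMask(arr, spacing = rep(spacing, 3))
  if (axis == 3) return(m)
  BinaryMask(aperm(arr, if (axis == 1) c(3, 2, 1) else c(1, 3, 2)),
             spacing = rep(spacing, 3))
}

# physical positions (mm) of linear voxel indices of a grid object
voxelLinearToMm <- function(lin, vol) {
  arr <- arrayInd(lin, gridDim(vol))
  sweep(sweep(arr - 1, 2, voxelSpacing(vol), "*"), 2, voxelOrigin(vol), "+")
}

diceCoefficient <- function(a, b) {
  a <- if (is(a, "BinaryMask")) voxelData(a) > 0 else a > 0
  b <- if (is(b, "BinaryMask")) voxelData(b) > 0 else b > 0
  2 * sum(a & b) / (sum(a) + sum(b))
}
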