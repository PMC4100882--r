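# Morphometry: volume, area profile, principal axes, inscribed sphere.

test_that("mask volume is voxel count times voxel volume", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(maskVolume(BinaryMask(one)), 0.001)
  expect_equal(maskVolume(BinaryMask(array(FALSE, c(3, 3, 3)))), 0)
  # digitized sphere r = 10 mm at 0.5 mm spacing: within 1% of 4/3 pi r^3
  ball <- digitizedBall(radius = 10, spacing = 0.5)
  expect_equal(maskVolume(ball), 4 / 3 * pi * 10^3 / 1000,
               tolerance = 0.01)
})

test_that("area profiles follow the analytic cross-sections", {
  cyl <- digitizedCylinder(radius = 10, length = 60, spacing = 1)
  prof <- areaProfile(cyl)
  expect_identical(nrow(prof), 60L)
  expect_true(all(abs(prof$area_mm2 - pi * 100) / (pi * 100) < 0.03))
  # a cone tapers monotonically
  n <- 40L
  arr <- array(FALSE, c(41, 41, n))
  cc <- seq_len(41) - 21
  for (k in seq_len(n)) {
    r <- 15 * (1 - (k - 1) / n)
    arr[, , k] <- outer(cc^2, cc^2, `+`) <= r^2
  }
  cone <- BinaryMask(arr)
  pc <- areaProfile(cone)
  expect_true(all(diff(pc$area_mm2) <= 0))
  # tear-shaped phantom: profile peaks near the generated max-diameter depth
  ph <- generatePhantom(phantomSpec(
    blockShapeMm = c(90, 90, 140), voxelSpacingMm = 1,
    cavityFamily = "tear_shaped",
    cavityParams = list(max_radius_mm = 25, max_depth_mm = 54,
                        length_mm = 120),
    noiseSdHu = 0, seed = 8L))
  prof2 <- areaProfile(ph$cavityMask, zRefMm = ph$truth@entryZMm)
  expect_lt(abs(prof2$depth_mm[which.max(prof2$area_mm2)] - 54), 5)
})

test_that("principal axes are recovered, including under rotation", {
  cyl <- digitizedCylinder(radius = 8, length = 100)
  ax <- principalAxis(cyl)
  expect_lt(acos(abs(sum(ax * c(0, 0, 1)))) * 180 / pi, 0.5)
  # the same cylinder tilted 10 degrees about y (via the phantom renderer)
  ph <- generatePhantom(phantomSpec(
    blockShapeMm = c(90, 90, 130), voxelSpacingMm = 1,
    cavityFamily = "cylinder",
    cavityParams = list(radius_mm = 8, length_mm = 100, tilt_deg = 10),
    noiseSdHu = 0, seed = 12L))
  ax2 <- principalAxis(ph$cavityMask)
  want <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  expect_lt(acos(abs(sum(ax2 * want))) * 180 / pi, 0.5)
  # a sphere has no meaningful axis: degenerate flag + warning
  ball <- digitizedBall(radius = 6, spacing = 1)
  expect_warning(axb <- principalAxis(ball), "ill-defined")
  expect_true(attr(axb, "degenerate"))
  expect_error(principalAxis(BinaryMask(array(FALSE, c(4, 4, 4)))),
               "too small")
})

test_that("deflection angle matches the generated tilt and folds into
           [0, 90]", {
  cyl <- digitizedCylinder(radius = 8, length = 100)
  expect_equal(as.numeric(deflectionAngle(cyl, cyl)), 0)
  # 6 degree tilt (the magnitude typical of a tumbling bullet)
  ph <- generatePhantom(phantomSpec(
    blockShapeMm = c(100, 100, 140), voxelSpacingMm = 1,
    cavityFamily = "cylinder",
    cavityParams = list(radius_mm = 8, length_mm = 110, tilt_deg = 6),
    noiseSdHu = 0, seed = 15L))
  ang <- deflectionAngle(ph$cavityMask, ph$blockMask)
  expect_lt(abs(as.numeric(ang) - 6), 1)
  # orthogonal rods give 90 degrees
  rodZ <- digitizedCylinder(radius = 3, length = 60, axis = 3)
  rodX <- BinaryMask(aperm(voxelData(rodZ), c(3, 2, 1)),
                     spacing = voxelSpacing(rodZ))
  # pad both onto a common cube
  n <- max(gridDim(rodZ))
  pad <- function(m) {
    a <- array(FALSE, c(n, n, n))
    d <- gridDim(m)
    a[1:d[1], 1:d[2], 1:d[3]] <- voxelData(m)
    BinaryMask(a)
  }
  expect_equal(as.numeric(deflectionAngle(pad(rodZ), pad(rodX))), 90,
               tolerance = 0.5)
})

test_that("the maximal inscribed sphere matches analytic solids", {
  # digitized sphere r = 12: radius within 1 voxel, centre at the middle
  ball <- digitizedBall(radius = 12, spacing = 1, pad = 3)
  s <- maxInscribedSphere(ball)
  expect_lt(abs(s$radius_mm - 12), 1)
  ctrTrue <- rep(gridDim(ball)[1] / 2 - 0.5, 3) # centre of the cube
  expect_true(all(abs(s$center_mm - ctrTrue) <= 1))
  # axis-aligned cylinder r = 8: radius within 1 voxel, centre on the axis
  cyl <- digitizedCylinder(radius = 8, length = 100, spacing = 1, pad = 4)
  s2 <- maxInscribedSphere(cyl)
  expect_lt(abs(s2$radius_mm - 8), 1)
  expect_lt(abs(s2$center_mm[1] - (gridDim(cyl)[1] / 2 - 0.5)), 1)
  expect_lt(abs(s2$center_mm[2] - (gridDim(cyl)[2] / 2 - 0.5)), 1)
  # single-voxel cavity: roughly half a voxel, centred on that voxel
  one <- array(FALSE, c(7, 7, 7)); one[4, 4, 4] <- TRUE
  s3 <- maxInscribedSphere(BinaryMask(one))
  expect_equal(s3$radius_mm, 1, tolerance = 1e-9) # nearest background centre
  expect_equal(s3$center_mm, c(3, 3, 3))
  expect_error(maxInscribedSphere(BinaryMask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("sphere radius is bounded by the cavity bounding box", {
  ph <- generatePhantom(phantomSpec(
    blockShapeMm = c(90, 90, 140), voxelSpacingMm = 1,
    cavityFamily = "tear_shaped",
    cavityParams = list(max_radius_mm = 22, max_depth_mm = 50,
                        length_mm = 110),
    noiseSdHu = 0, seed = 19L))
  s <- maxInscribedSphere(ph$cavityMask)
  bitsum <- function(f) diff(range(which(f))) + 1
  bits <- voxelData(ph$cavityMask)
  ext <- c(bitsum(apply(bits, 1, any)), bitsum(apply(bits, 2, any)),
           bitsum(apply(bits, 3, any)))
  expect_lte(s$radius_mm, min(ext) / 2 + 1e-9)
})

test_that("metric consistency: volume equals the integrated area
           profile", {
  ph <- generatePhantom(phantomSpec(
    blockShapeMm = c(100, 100, 150), voxelSpacingMm = 1,
    cavityFamily = "tumbling_spindle",
    cavityParams = list(max_radius_mm = 20, max_depth_mm = 90,
                        length_mm = 125, width_mm = 25, tilt_deg = 3),
    noiseSdHu = 0, seed = 23L))
  m <- cavityMetrics(ph$cavityMask, ph$blockMask)
  dz <- voxelSpacing(ph$cavityMask)[3]
  expect_equal(m@volumeMl, sum(m@areaProfile$area_mm2) * dz / 1000,
               tolerance = 0.05)
  expect_gte(m@deflectionDeg, 0); expect_lte(m@deflectionDeg, 90)
})
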