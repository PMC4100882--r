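# Segmentation of block, cavity and fragments, and the streak exclusion.

test_that("soap intensity estimation is robust to noise and exact
           without it", {
  ph0 <- smallCylinderPhantom(noise = 0)
  expect_identical(estimateSoapIntensity(ph0$volume), 100)
  ph <- smallCylinderPhantom(noise = 5, seed = 4L)
  est <- estimateSoapIntensity(ph$volume)
  expect_gt(est, 95); expect_lt(est, 105)
  # an all-soap volume: the estimate is its median
  allSoap <- VoxelVolume(array(100 + rnorm(1000, 0, 3), c(10, 10, 10)))
  expect_equal(estimateSoapIntensity(allSoap),
               median(voxelData(allSoap)[voxelData(allSoap) >
                 soapCT:::.otsuThreshold(voxelData(allSoap))]))
  expect_error(estimateSoapIntensity(VoxelVolume(array(0, c(4, 4, 4)))),
               "degenerate")
})

test_that("block segmentation recovers the rendered block", {
  ph <- smallCylinderPhantom(noise = 10, seed = 5L)
  blk <- segmentBlock(ph$volume)
  expect_gte(diceCoefficient(blk, ph$blockMask), 0.99)
  # cavity voxels are below threshold, hence not in the block mask
  expect_identical(sum(voxelData(blk) & voxelData(ph$cavityMask)), 0L)
  # all-air volume: nothing to segment
  air <- VoxelVolume(array(-1000 + rnorm(8000, 0, 5), c(20, 20, 20)))
  expect_error(segmentBlock(air, soapHu = 100), "no block found")
})

test_that("cavity segmentation recovers the rendered cavity in seeded
           and automatic modes", {
  ph <- smallCylinderPhantom(noise = 10, seed = 6L)
  blk <- segmentBlock(ph$volume)
  zAny <- which(apply(voxelData(ph$cavityMask), 3, any))
  cavSeeded <- segmentCavity(ph$volume, blk, firstSlice = min(zAny),
                             lastSlice = max(zAny))
  expect_gte(diceCoefficient(cavSeeded, ph$cavityMask), 0.98)
  cavAuto <- segmentCavity(ph$volume, blk)
  expect_gte(diceCoefficient(cavAuto, ph$cavityMask), 0.98)
  # block and cavity partition: thresholds are mutually exclusive
  expect_identical(sum(voxelData(blk) & voxelData(cavAuto)), 0L)
})

test_that("a single-slice range yields the analytic cross-section", {
  ph <- smallCylinderPhantom(radius = 8, noise = 0)
  blk <- segmentBlock(ph$volume)
  zmid <- which(apply(voxelData(ph$cavityMask), 3, any))
  k <- zmid[round(length(zmid) / 2)]
  cav1 <- segmentCavity(ph$volume, blk, firstSlice = k, lastSlice = k)
  area <- sum(voxelData(cav1)) * prod(voxelSpacing(cav1)[1:2])
  expect_equal(area, pi * 8^2, tolerance = 0.05)
})

test_that("an intact block has no cavity", {
  spec <- phantomSpec(blockShapeMm = c(50, 50, 70), voxelSpacingMm = 2,
                      cavityFamily = "cylinder",
                      cavityParams = list(radius_mm = 3, length_mm = 40),
                      noiseSdHu = 0, seed = 2L)
  ph <- generatePhantom(spec)
  # overwrite the cavity with soap: an intact block
  v <- voxelData(ph$volume)
  v[voxelData(ph$cavityMask)] <- 100
  intact <- VoxelVolume(v, voxelSpacing(ph$volume), voxelOrigin(ph$volume))
  blk <- segmentBlock(intact)
  expect_error(segmentCavity(intact, blk), "no cavity")
})

test_that("fragments are found, counted and deterministically labelled", {
  spec <- phantomSpec(blockShapeMm = c(90, 90, 130), voxelSpacingMm = 1,
                      cavityFamily = "cylinder",
                      cavityParams = list(radius_mm = 6, length_mm = 100),
                      nFragments = 5L, fragmentRadiusRangeMm = c(2, 3),
                      noiseSdHu = 0, seed = 31L)
  ph <- generatePhantom(spec)
  fr <- segmentFragments(ph$volume)
  tab <- fragmentTable(fr)
  expect_identical(nrow(tab), 5L)
  expect_true(all(tab$max_hu > 2000))
  # labels sorted by centroid z
  expect_true(!is.unsorted(tab$centroid_z_mm))
  # centroids within one voxel of the true centres
  truth <- ph$truth@fragmentCentersMm[
    order(ph$truth@fragmentCentersMm[, 3]), ]
  err <- sqrt(rowSums((as.matrix(tab[, c("centroid_x_mm", "centroid_y_mm",
                                         "centroid_z_mm")]) - truth)^2))
  expect_true(all(err < 1))
  # no voxel above threshold -> empty set, not an error
  fr0 <- segmentFragments(smallCylinderPhantom(noise = 0)$volume)
  expect_identical(nrow(fragmentTable(fr0)), 0L)
  expect_identical(countedFragments(fr0), 0L)
})

test_that("face-sharing high-intensity voxels merge under
           26-connectivity", {
  v <- array(-1000, c(10, 10, 10))
  v[4, 4, 4] <- 3000; v[5, 4, 4] <- 3000   # share a face
  v[8, 8, 8] <- 3000; v[9, 9, 9] <- 3000   # share only a corner
  fr <- segmentFragments(VoxelVolume(v))
  expect_identical(nrow(fragmentTable(fr)), 2L)
})

test_that("streak exclusion flags small specks near large fragments and
           is monotone in the proximity radius", {
  # hand-built scene: one large fragment, one speck at 2 mm, one lone speck
  v <- array(-1000, c(40, 40, 20))
  v[10:14, 10:14, 8:12] <- 3000      # large (125 mm^3)
  v[17, 12, 10] <- 3000              # speck 2 mm from the large surface
  v[35, 35, 15] <- 3000              # lone speck, far away
  fr <- segmentFragments(VoxelVolume(v))
  expect_identical(nrow(fragmentTable(fr)), 3L)
  fr5 <- applyStreakExclusion(fr, smallMaxMm3 = 8, proximityMm = 5)
  tab <- fragmentTable(fr5)
  expect_identical(countedFragments(fr5), 2L)
  expect_false(tab$counted[tab$n_voxels == 1 & tab$centroid_x_mm < 20])
  expect_true(tab$counted[tab$centroid_x_mm > 30])  # lone speck counted
  # proximity 0 keeps the raw component count
  expect_identical(countedFragments(applyStreakExclusion(fr, 8, 0)), 3L)
  # counted number non-increasing as proximity grows
  counts <- vapply(c(0, 2, 5, 20, 60), function(p)
    countedFragments(applyStreakExclusion(fr, 8, p)), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(applyStreakExclusion(fr, -1, 5), "non-negative")
})

test_that("generated streak specks are excluded so counted fragments
           equal the ground truth", {
  spec <- phantomSpec(blockShapeMm = c(100, 100, 140), voxelSpacingMm = 1,
                      cavityFamily = "cylinder",
                      cavityParams = list(radius_mm = 7, length_mm = 110),
                      nFragments = 3L, fragmentRadiusRangeMm = c(1.8, 3.4),
                      streakArtifacts = TRUE, noiseSdHu = 10, seed = 17L)
  ph <- generatePhantom(spec)
  fr <- applyStreakExclusion(segmentFragments(ph$volume))
  expect_identical(countedFragments(fr), 3L)
})
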