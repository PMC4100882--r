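# Phantom generator: profiles, design enumeration, determinism, rendering.

test_that("cavity profiles honour their family shape contracts", {
  # cylinder: constant radius everywhere
  expect_equal(cavityProfile("cylinder",
                             list(radius_mm = 5, length_mm = 100),
                             c(0, 33, 100)), rep(5, 3))
  # boundary: every family ends at its stated exit radius (the neck, or
  # the cylinder radius)
  expect_equal(cavityProfile("tumbling_spindle",
    list(neck_radius_mm = 4, max_radius_mm = 30, max_depth_mm = 200,
         length_mm = 300, width_mm = 30), 300), 4, tolerance = 1e-3)
  expect_equal(cavityProfile("tear_shaped",
    list(neck_radius_mm = 4, max_radius_mm = 30, max_depth_mm = 126,
         length_mm = 280), 280), 4)
  # tumbling spindle peaks at its max-diameter depth (dense evaluation)
  d <- seq(0, 300, by = 0.5)
  r <- cavityProfile("tumbling_spindle",
    list(max_depth_mm = 200, length_mm = 300), d)
  expect_lt(abs(d[which.max(r)] - 200), 5)
  # early opening reaches near-max radius within the first quarter
  d2 <- seq(0, 260, by = 0.5)
  r2 <- cavityProfile("early_opening", list(length_mm = 260), d2)
  expect_gt(max(r2[d2 <= 65]), 0.95 * max(r2))
  # tear shape rises smoothly then tapers: unimodal
  r3 <- cavityProfile("tear_shaped", list(length_mm = 280), d <- seq(0, 280))
  peak <- which.max(r3)
  expect_true(all(diff(r3[1:peak]) >= -1e-9))
  expect_true(all(diff(r3[peak:length(r3)]) <= 1e-9))
  # contracts: unknown family and out-of-range depth are rejected
  expect_error(cavityProfile("banana", list(), 1), "one of")
  expect_error(cavityProfile("cylinder", list(length_mm = 50), 60),
               "within")
})

test_that("voxelized cylinder volume matches the analytic value and
           converges as spacing shrinks", {
  # the example cylinder: pi * 10^2 * 100 / 1000 = 31.416 mL at 1 mm
  analytic10 <- pi * 10^2 * 100 / 1000
  ph10 <- smallCylinderPhantom(radius = 10, length = 100, spacing = 1,
                               block = c(60, 60, 110))
  expect_equal(ph10$truth@volumeMl, analytic10, tolerance = 1e-6)
  expect_lt(abs(maskVolume(ph10$cavityMask) - analytic10) / analytic10,
            0.02)
  # convergence as spacing shrinks; a lattice-incommensurate radius and
  # block keep the alignment generic (symmetric alignments can tie the
  # discretization error exactly across spacings)
  analytic <- pi * 9.7^2 * 100 / 1000
  errs <- vapply(c(2, 1, 0.5), function(sp) {
    ph <- smallCylinderPhantom(radius = 9.7, length = 100, spacing = sp,
                               block = c(61.3, 60.7, 110))
    expect_equal(ph$truth@volumeMl, analytic, tolerance = 1e-6)
    abs(maskVolume(ph$cavityMask) - analytic) / analytic
  }, numeric(1))
  expect_true(all(diff(errs) < 0)) # strictly decreasing error
})

test_that("zero tilt gives an axis along the block long axis", {
  ph <- smallCylinderPhantom(tilt = 0)
  expect_equal(ph$truth@axis, c(0, 0, 1))
  expect_identical(ph$truth@tiltDeg, 0)
  expect_equal(sqrt(sum(ph$truth@axis^2)), 1)
})

test_that("generation is bit-identical for a fixed seed and differs
           across seeds", {
  spec <- phantomSpec(blockShapeMm = c(60, 60, 90), voxelSpacingMm = 2,
                      cavityFamily = "tear_shaped",
                      cavityParams = list(max_radius_mm = 15,
                                          max_depth_mm = 32,
                                          length_mm = 70),
                      nFragments = 2L, streakArtifacts = TRUE,
                      noiseSdHu = 12, seed = 21L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  spec2 <- spec; spec2@seed <- 22L
  c <- generatePhantom(spec2)
  expect_false(identical(voxelData(a$volume), voxelData(c$volume)))
  # the generator must not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(generatePhantom(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("fragment and streak voxels obey their intensity contracts", {
  spec <- phantomSpec(blockShapeMm = c(80, 80, 120), voxelSpacingMm = 1,
                      cavityFamily = "cylinder",
                      cavityParams = list(radius_mm = 6, length_mm = 90),
                      nFragments = 4L, streakArtifacts = TRUE,
                      noiseSdHu = 0, seed = 9L)
  ph <- generatePhantom(spec)
  v <- voxelData(ph$volume)
  ctr <- ph$truth@fragmentCentersMm
  rad <- ph$truth@fragmentRadiiMm
  expect_identical(nrow(ctr), 4L)
  # all voxels inside the true spheres are at fragment intensity
  sp <- voxelSpacing(ph$volume); org <- voxelOrigin(ph$volume)
  for (i in seq_len(nrow(ctr))) {
    ci <- round((ctr[i, ] - org) / sp) + 1
    expect_gt(v[ci[1], ci[2], ci[3]], 2000)
  }
  # streak voxels (+-500 around soap, and specks) lie outside all spheres
  streakIdx <- which(abs(v - 600) < 1e-9 | abs(v + 400) < 1e-9)
  if (length(streakIdx)) {
    pos <- voxelLinearToMm(streakIdx, ph$volume)
    for (i in seq_len(nrow(ctr))) {
      dd <- sqrt(colSums((t(pos) - ctr[i, ])^2))
      expect_true(all(dd > rad[i]))
    }
  }
})

test_that("invalid specs are rejected", {
  expect_error(phantomSpec(fragmentHu = 1500), "2000")
  expect_error(phantomSpec(soapHu = -1500), "between")
  expect_error(phantomSpec(voxelSpacingMm = c(1, -1, 1)), "positive")
  # cavity longer than the block
  expect_error(phantomSpec(blockShapeMm = c(100, 100, 100),
                           cavityFamily = "cylinder",
                           cavityParams = list(radius_mm = 5,
                                               length_mm = 150)),
               "longer|fit")
  # cavity wider than the block
  expect_error(phantomSpec(blockShapeMm = c(40, 40, 200),
                           cavityFamily = "cylinder",
                           cavityParams = list(radius_mm = 30,
                                               length_mm = 100)),
               "fit")
})

test_that("design enumeration matches the factorial layout", {
  # full design: 4 bullets x 4 speeds x 2 shots per configuration
  d <- enumerateDesign(c("ILS", "TAG", "TSX", "NVU"),
                       list(ILS = c(600, 700, 800, 900),
                            TAG = c(550, 650, 750, 850),
                            TSX = c(550, 650, 750, 850),
                            NVU = c(500, 600, 700, 800)),
                       repetitions = 2)
  expect_identical(nrow(d), 32L)
  expect_identical(nrow(unique(d[, c("bullet", "speed_mps")])), 16L)
  # 1 bullet, 4 speeds, 2 reps -> 8 stubs
  expect_identical(nrow(enumerateDesign("X", c(1, 2, 3, 4), 2)), 8L)
  # deterministic ordering: bullet, then speed ascending, then repetition
  d2 <- enumerateDesign(c("B", "A"), list(B = c(700, 600), A = c(500)), 2)
  expect_identical(d2$bullet, c("B", "B", "B", "B", "A", "A"))
  expect_identical(d2$speed_mps, c(600, 600, 700, 700, 500, 500))
  expect_identical(d2$repetition, rep(1:2, 3))
  expect_error(enumerateDesign(character(0), c(1)), "empty")
  expect_error(enumerateDesign("A", c(1), 0), "repetitions")
})
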