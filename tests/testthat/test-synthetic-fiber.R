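test_that("notch opening angle follows tan(theta/2) = w/(2h)", {
  expect_equal(notchAngle(2, 1), 90)
  # the imaged bundle notch: 40 um opening, 15 um depth
  expect_equal(notchAngle(40, 15), 2 * atan(40 / 30) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(notchAngle(40, 15), 106.26, tolerance = 1e-4)
  # the imaged elementary-fiber notch: 7.7 um opening, 2.8 um depth
  expect_equal(notchAngle(7.7, 2.8), 107.9453, tolerance = 1e-4)
  expect_error(notchAngle(0, 1), "positive")
  expect_error(notchAngle(3, -2), "positive")
  expect_error(notchGeometry("V", width = 10, depth = 0), "positive")
})

test_that("generated fibers are two-valued with the requested geometry", {
  sp <- fiberSpec(diameter = 40, shapeFactor = 1, length = 80,
                  voxelSize = 1)
  vol <- generateFiber(sp, seed = 1)
  expect_setequal(unique(as.vector(voxelData(vol))), c(0L, 255L))
  seg <- segmentVolume(vol, openingRadius = 0)
  fd <- fiberDescriptors(seg)
  expect_equal(fd$shapeFactor, 1, tolerance = 0.05)
  expect_equal(fd$diameter, 40, tolerance = 0.02)
  # no lumen -> porosity 0
  expect_equal(porosityFraction(seg), 0)
  # explicit dims that cannot contain the fiber
  expect_error(generateFiber(sp, seed = 1, dims = c(80, 20, 20)),
               "does not fit")
})

test_that("lumen porosity is recovered within one percentage point", {
  sp <- fiberSpec(diameter = 36, length = 108, voxelSize = 1,
                  lumen = TRUE, lumenFraction = 0.10)
  for (seed in c(1, 2)) {
    vol <- generateFiber(sp, seed = seed)
    p <- porosityFraction(segmentVolume(vol, openingRadius = 0))
    expect_lt(abs(p - 0.10), 0.01)
  }
  # lumen absent
  sp0 <- fiberSpec(diameter = 36, length = 72, voxelSize = 1)
  expect_equal(
    porosityFraction(segmentVolume(generateFiber(sp0, 1),
                                   openingRadius = 0)), 0)
})

test_that("notch carving removes the prescribed in-plane area", {
  slab <- SegmentedVolume(array(255L, c(100, 40, 20)), 1)
  before <- sum(solidCount <- voxelData(slab) == 255)
  sv <- carveNotch(slab, suppressWarnings(
    notchGeometry("V", width = 40, depth = 15)))
  remV <- (before - sum(voxelData(sv) == 255)) / 20
  expect_equal(remV, 40 * 15 / 2, tolerance = 0.10)
  su <- carveNotch(slab, suppressWarnings(
    notchGeometry("U", width = 40, depth = 15)))
  remU <- (before - sum(voxelData(su) == 255)) / 20
  expect_equal(remU, pi * 20 * 15 / 2, tolerance = 0.10)
  # removal only converts solid to air
  expect_true(all(voxelData(sv)[voxelData(slab) == 0L] == 0L))
  # a one-voxel sliver still strictly decreases the volume
  s1 <- carveNotch(slab, suppressWarnings(
    notchGeometry("V", width = 4, depth = 1)))
  expect_lt(sum(voxelData(s1) == 255), before)
  # notch through the whole width is rejected
  expect_error(carveNotch(slab, suppressWarnings(
    notchGeometry("V", width = 40, depth = 60))), "through")
})

test_that("carving then measuring the notch reproduces the opening angle", {
  for (geom in list(c(20, 10), c(14, 12))) {
    w <- geom[1]; h <- geom[2]
    slab <- SegmentedVolume(array(255L, c(80, 30, 10)), 1)
    sv <- carveNotch(slab, suppressWarnings(
      notchGeometry("V", width = w, depth = h)))
    removed <- voxelData(slab) == 255 & voxelData(sv) == 0
    # depth: radial extent of removal; opening: axial extent at the surface
    ys <- apply(removed, 2, any)
    h_meas <- sum(ys)
    surface <- max(which(ys))
    w_meas <- sum(apply(removed[, surface, , drop = FALSE], 1, any))
    expect_lt(abs(notchAngle(w_meas, h_meas) - notchAngle(w, h)), 5)
  }
})

test_that("surface roughness has the requested RMS and is reproducible", {
  sp <- fiberSpec(diameter = 40, length = 120, voxelSize = 1)
  v0 <- generateFiber(sp, seed = 1)
  expect_identical(voxelData(addSurfaceRoughness(v0, 0, 10)),
                   voxelData(v0))
  v1 <- addSurfaceRoughness(v0, 2.5, 10, seed = 5)
  v2 <- addSurfaceRoughness(v0, 2.5, 10, seed = 5)
  expect_identical(voxelData(v1), voxelData(v2))
  v3 <- addSurfaceRoughness(v0, 2.5, 10, seed = 6)
  expect_false(identical(voxelData(v1), voxelData(v3)))
  rms <- boundaryDeviationRMS(v0, v1)
  expect_lt(abs(rms - 2.5), 0.2 * 2.5)
})

test_that("presets carry the printed fiber descriptors", {
  px <- fiberPreset("FXU4")
  expect_equal(px$spec@lumenFraction, 0.09)
  expect_equal(px$spec@shapeFactor, 3.23)
  expect_equal(px$spec@diameter, 232)
  pf <- fiberPreset("FU")
  expect_equal(pf$spec@shapeFactor, 1.28)
  expect_equal(pf$spec@diameter, 44)
  expect_equal(pf$spec@lumenFraction, 0.04)
  pv <- fiberPreset("FIV15")
  expect_false(pv$spec@lumen)
  expect_equal(pv$spec@diameter, 18)
  p9 <- fiberPreset("FU19")
  expect_false(p9$spec@lumen)
  expect_equal(p9$spec@diameter, 23)
  expect_equal(p9$spec@shapeFactor, 1.78)
  expect_error(fiberPreset("NOPE"))
  # rescaling: the diameter spans the requested number of voxels
  ps <- fiberPreset("FU", targetDiameterVoxels = 22)
  expect_equal(ps$spec@diameter / ps$spec@voxelSize, 22)
})

test_that("generator parameters are recovered by the morphometrics", {
  fx <- preset_fixture("FU", dvox = 32, ld = 3, seed = 1)
  expect_lt(abs(porosityFraction(fx$seg) - 0.04), 0.01)
  fd <- fiberDescriptors(fx$seg)
  expect_equal(fd$shapeFactor, 1.28, tolerance = 0.1 / 1.28)
  lum <- extractLumen(fx$seg)
  st <- sliceEllipseStats(lum, voxelSize(fx$seg))
  expect_equal(st@summary$meanAspect, 2, tolerance = 0.15)
})
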