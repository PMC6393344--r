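test_that("segmentation recovers a two-phase volume from noisy gray data", {
  sp <- fiberSpec(diameter = 30, length = 60, voxelSize = 1)
  vol <- generateFiber(sp, seed = 1)
  clean <- segmentVolume(vol, openingRadius = 0)
  # already two-valued, radius 0: unchanged
  expect_identical(voxelData(clean), voxelData(vol))
  # additive Gaussian gray noise, sigma = 20 levels
  g <- voxelData(vol)
  noisy <- with(list(), {
    set.seed(42)
    pmin(pmax(g + round(rnorm(length(g), 0, 20)), 0), 255)
  })
  nvol <- VoxelVolume(array(noisy, dim(g)), 1)
  nseg <- segmentVolume(nvol, openingRadius = 1)
  vf_clean <- mean(voxelData(clean) == 255)
  vf_noisy <- mean(voxelData(nseg) == 255)
  expect_lt(abs(vf_noisy - vf_clean) / vf_clean, 0.01)
  # constant volume needs an explicit threshold
  flat <- VoxelVolume(array(100L, c(4, 4, 4)), 1)
  expect_error(segmentVolume(flat), "threshold")
  expect_s4_class(segmentVolume(flat, threshold = 50), "SegmentedVolume")
})

test_that("morphological opening removes isolated speckles", {
  g <- array(0L, c(20, 20, 20))
  g[5:15, 5:15, 5:15] <- 255L     # solid block
  set.seed(7)
  spk <- cbind(sample(17:20, 10, TRUE), sample(1:20, 10, TRUE),
               sample(1:20, 10, TRUE))
  g[spk] <- 255L                   # isolated speckles outside the block
  vol <- VoxelVolume(g, 1)
  seg0 <- segmentVolume(vol, threshold = 127, openingRadius = 0)
  seg1 <- segmentVolume(vol, threshold = 127, openingRadius = 1)
  lab0 <- fibrekin:::cpp_label3d(as.vector(voxelData(seg0) == 255),
                                 dim(g))
  lab1 <- fibrekin:::cpp_label3d(as.vector(voxelData(seg1) == 255),
                                 dim(g))
  expect_gt(max(lab0), 1)
  expect_equal(max(lab1), 1)
})

test_that("corner flooding separates lumen from exterior air", {
  # solid cylinder: no cavity
  sp <- fiberSpec(diameter = 20, length = 30, voxelSize = 1)
  seg <- segmentVolume(generateFiber(sp, 1), openingRadius = 0)
  expect_equal(max(extractLumen(seg)), 0)
  # tube: one label spanning the full axial extent
  spt <- fiberSpec(diameter = 24, length = 40, voxelSize = 1,
                   lumen = TRUE, lumenFraction = 0.1, lumenWaviness = 0)
  segt <- segmentVolume(generateFiber(spt, 1), openingRadius = 0)
  lab <- extractLumen(segt)
  expect_equal(max(lab), 1)
  axial <- apply(lab > 0, 1, any)
  expect_true(all(axial))
  # two parallel disjoint tubes: two labels with the right voxel counts
  g <- array(0L, c(20, 30, 30))
  yy <- slice.index(g, 2); zz <- slice.index(g, 3)
  solid <- (yy - 15)^2 + (zz - 15)^2 <= 13^2
  t1 <- (yy - 10)^2 + (zz - 15)^2 <= 2^2
  t2 <- (yy - 20)^2 + (zz - 15)^2 <= 3^2
  g[solid] <- 255L; g[t1 | t2] <- 0L
  segg <- SegmentedVolume(g, 1)
  lab2 <- extractLumen(segg)
  expect_equal(max(lab2), 2)
  sizes <- sort(tabulate(lab2[lab2 > 0]))
  expect_equal(sizes, sort(c(sum(t1), sum(t2))))
})

test_that("porosity equals the brute-force voxel count and is axis-stable", {
  spt <- fiberSpec(diameter = 24, length = 40, voxelSize = 1,
                   lumen = TRUE, lumenFraction = 0.08)
  segt <- segmentVolume(generateFiber(spt, 3), openingRadius = 0)
  lab <- extractLumen(segt)
  # independent counting oracle
  nl <- 0L; ns <- 0L
  d <- dim(lab)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (lab[i, j, k] > 0L) nl <- nl + 1L
    else if (voxelData(segt)[i, j, k] == 255L) ns <- ns + 1L
  }
  expect_identical(porosityFraction(segt, lab), nl / (nl + ns))
  # swapping the two transverse axes leaves porosity unchanged
  perm <- SegmentedVolume(aperm(voxelData(segt), c(1, 3, 2)),
                          voxelSize(segt))
  expect_equal(porosityFraction(perm), porosityFraction(segt))
  # enclosed cavity: porosity invariant under any axis permutation
  g <- array(0L, c(24, 24, 24))
  ii <- slice.index(g, 1); jj <- slice.index(g, 2); kk <- slice.index(g, 3)
  g[(ii - 12)^2 + (jj - 12)^2 + (kk - 12)^2 <= 10^2] <- 255L
  g[(ii - 12)^2 + (jj - 12)^2 + (kk - 12)^2 <= 4^2] <- 0L
  p0 <- porosityFraction(SegmentedVolume(g, 1))
  for (ax in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(porosityFraction(SegmentedVolume(aperm(g, ax), 1)), p0)
  # no solid: undefined porosity
  expect_error(porosityFraction(SegmentedVolume(array(0L, c(3, 3, 3)), 1)),
               "undefined")
})

test_that("exterior air + lumen + solid partition the volume exactly", {
  fx <- preset_fixture("FXU4", dvox = 16, ld = 1.5, seed = 2)
  lab <- extractLumen(fx$seg)
  solid <- voxelData(fx$seg) == 255L
  lumen <- lab > 0L
  exterior <- !solid & !lumen
  expect_equal(sum(solid) + sum(lumen) + sum(exterior),
               prod(dim(lab)))
  expect_false(any(solid & lumen))
  # every exterior-air voxel is truly connected to the lateral boundary
  expect_false(any(lumen & !voxelData(fx$seg) == 0L))
})

test_that("moment ellipse fits recover area and aspect of round shapes", {
  mk <- function(a, b, n = 8) {
    g <- array(0L, c(n, 64, 64))
    jj <- slice.index(g, 2); kk <- slice.index(g, 3)
    sol <- (jj - 32)^2 / (a + 6)^2 + (kk - 32)^2 / (b + 6)^2 <= 1
    lum <- (jj - 32)^2 / a^2 + (kk - 32)^2 / b^2 <= 1
    g[sol] <- 255L; g[lum] <- 0L
    extractLumen(SegmentedVolume(g, 1))
  }
  # circular lumen, radius 10
  st <- sliceEllipseStats(mk(10, 10), 1)
  expect_equal(st@summary$meanArea, pi * 100, tolerance = 0.05)
  expect_equal(st@summary$meanAspect, 1, tolerance = 0.05)
  # elliptical lumen, semi-axes 20 and 10
  st2 <- sliceEllipseStats(mk(20, 10), 1)
  expect_equal(st2@summary$meanAspect, 2, tolerance = 0.05)
  # constant tube: mean equals median for both attributes
  expect_equal(st2@summary$meanArea, st2@summary$medianArea)
  expect_equal(st2@summary$meanAspect, st2@summary$medianAspect)
  # slices with fewer than 5 lumen voxels are skipped and counted
  lab <- mk(10, 10)
  lab[3, , ] <- 0L
  idx <- which(lab[4, , ] > 0L)
  lab4 <- lab[4, , ]; lab4[idx[-(1:3)]] <- 0L
  lab[4, , ] <- lab4
  st3 <- sliceEllipseStats(lab, 1)
  expect_equal(st3@skippedSlices, 1L)
  expect_equal(nrow(st3@perSlice), 6L)
})

test_that("fiber descriptors scale with the volume", {
  sp <- fiberSpec(diameter = 50, length = 50, voxelSize = 1)
  seg <- segmentVolume(generateFiber(sp, 1), openingRadius = 0)
  fd <- fiberDescriptors(seg)
  expect_equal(fd$shapeFactor, 1, tolerance = 0.05)
  expect_equal(fd$diameter, 50, tolerance = 0.02)
  # isotropic upscaling doubles the diameter, preserves the shape factor
  sp2 <- fiberSpec(diameter = 50, length = 50, voxelSize = 0.5)
  fd2 <- fiberDescriptors(segmentVolume(generateFiber(sp2, 1),
                                        openingRadius = 0))
  expect_equal(fd2$diameter, fd$diameter, tolerance = 0.02)
  expect_equal(fd2$shapeFactor, 1, tolerance = 0.05)
})
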