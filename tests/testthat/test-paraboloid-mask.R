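test_that("sum projections collapse the out-of-plane axis correctly", {
  a <- array(runif(6 * 5 * 4), c(6, 5, 4))
  st <- resampleIsotropic(
    VoxelStack(list(wall = a), voxelSizeXY = 0.3, voxelSizeZ = 0.3))
  # single collapsed slice: the projection is that slice's plane
  pr <- sumProjection(st, "wall", "xz", sliceInterval = c(3, 3))
  expect_equal(pr@pixels, a[, 3, ])
  # constant stack, k slices: every pixel is k * c
  ac <- array(2.5, c(6, 5, 4))
  stc <- resampleIsotropic(
    VoxelStack(list(wall = ac), voxelSizeXY = 0.3, voxelSizeZ = 0.3))
  prc <- sumProjection(stc, "wall", "yz", sliceInterval = c(1, 3))
  expect_true(all(prc@pixels == 3 * 2.5))
  expect_error(sumProjection(st, "wall", "xz", sliceInterval = c(4, 2)),
               "interval")
})

test_that("projected wall signal is centred on the dome apex", {
  # a wall shell of constant thickness projects to a flat-topped profile,
  # so the apex is located by the signal centroid (exact for a dome
  # centred in the grid), not by the argmax of a plateau
  dome <- domeSpec(apexUm = c(6.375, 6.375, 1.1),
                   curvatures = c(0.05, 0.06))
  g <- makeDomeStack(dome, list(), dim = c(48, 52, 52),
                     voxelSizes = c(0.25, 0.25), seed = 2)
  iso <- asIso(g$stack)
  prx <- sumProjection(iso, "wall", "xz")
  topRows <- prx@pixels[seq_len(20), ]   # apical region only
  w <- colSums(topRows)
  xHat <- sum(w * (seq_along(w) - 1) * prx@pixelSize) / sum(w)
  expect_lt(abs(xHat - 6.375), 1.5 * prx@pixelSize)
})

test_that("fitParabola recovers exact and rotated parabolas", {
  pts <- makeOutlinePoints(c(0, 10), 0.05, tiltDeg = 0, n = 30,
                           noiseSd = 0, seed = 1)
  f0 <- fitParabola(pts)
  expect_equal(apexPosition(f0), c(0, 10), tolerance = 1e-6)
  expect_equal(curvature(f0), 0.05, tolerance = 1e-6)
  expect_lt(abs(f0@theta), 0.1)

  pts10 <- makeOutlinePoints(c(0, 10), 0.05, tiltDeg = 10, n = 30,
                             noiseSd = 0, seed = 1)
  f10 <- fitParabola(pts10)
  expect_lt(abs(f10@theta - 10), 0.1)
  expect_lt(abs(curvature(f10) - 0.05) / 0.05, 1e-3)
})

test_that("three symmetric points give the textbook parabola", {
  pts <- rbind(c(-10, 5), c(0, 0), c(10, 5))
  f <- fitParabola(pts, thetaRange = c(0, 0))
  expect_equal(curvature(f), 0.05, tolerance = 1e-12)
  expect_equal(apexPosition(f), c(0, 0), tolerance = 1e-9)
})

test_that("fitParabola is equivariant under translation and rotation", {
  base <- makeOutlinePoints(c(2, 4), 0.07, tiltDeg = 3, n = 40,
                            noiseSd = 0.05, seed = 8)
  f <- fitParabola(base)
  for (shift in list(c(5, -2), c(-11, 3))) {
    fs <- fitParabola(sweep(base, 2L, shift, `+`))
    expect_equal(apexPosition(fs), apexPosition(f) + shift,
                 tolerance = 1e-3)
    expect_equal(curvature(fs), curvature(f), tolerance = 1e-6)
  }
  for (phi in c(-6, 4)) {
    fr <- fitParabola(base %*% t(apexquant:::.rot2(phi)))
    expect_equal(fr@theta, f@theta + phi, tolerance = 0.1)
    expect_equal(curvature(fr), curvature(f), tolerance = 1e-4)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fitParabola(rbind(c(0, 0), c(1, 1))), "at least 3")
  line <- cbind(seq_len(5), 2 * seq_len(5))
  expect_error(fitParabola(line), "collinear")
})

test_that("buildParaboloid matches each view's quadratic term", {
  pXZ <- new("Parabola2D", apex = c(3, 8), curvature = 0.05, theta = 2,
             rss = 0, gof = 1)
  pYZ <- new("Parabola2D", apex = c(5, 12), curvature = 0.05, theta = 0,
             rss = 0, gof = 1)
  p3 <- buildParaboloid(pXZ, pYZ)
  expect_equal(p3@c1sq, 20)
  expect_equal(p3@c2sq, 20)
  expect_equal(apexPosition(p3), c(3, 5, 10))   # depth = mean(8, 12)
  expect_true(p3@lateralComplete)

  pXZ2 <- new("Parabola2D", apex = c(3, 8), curvature = 0.1, theta = 0,
              rss = 0, gof = 1)
  pOnly <- buildParaboloid(pXZ2, y0 = 4)
  expect_equal(pOnly@c2sq, pOnly@c1sq)
  expect_equal(pOnly@c1sq, 10)
  expect_false(pOnly@lateralComplete)
  expect_error(buildParaboloid(pXZ2), "y0 is required")
})

test_that("curvature inflation divides a by alpha and shrinks the mask", {
  p <- new("Paraboloid3D", apex = c(6.3, 6.3, 1.1), c1sq = 20, c2sq = 20,
           theta = 0, lateralComplete = TRUE)
  pi2 <- inflateCurvature(p, 0.5)
  expect_equal(unname(curvature(pi2)["a1"]), 0.05 / 0.5)
  expect_equal(apexPosition(pi2), apexPosition(p))
  expect_error(inflateCurvature(p, 1), "strictly between")
  expect_error(inflateCurvature(p, 0), "strictly between")

  n0 <- sum(apexquant:::.paraboloidInterior(p, c(40, 50, 50), 0.25))
  n1 <- sum(apexquant:::.paraboloidInterior(pi2, c(40, 50, 50), 0.25))
  expect_lt(n1, n0)
})

test_that("masking zeroes exactly the brute-force exterior", {
  g <- smallDome(value = 1, seed = 13, tiltDeg = 7)
  iso <- asIso(g$stack)
  man <- g$manifest
  p <- new("Paraboloid3D", apex = man$apex_um, c1sq = man$c1sq_um2,
           c2sq = man$c2sq_um2, theta = man$tilt_deg,
           lateralComplete = TRUE)
  d <- dim(iso)
  oracle <- bruteForceInterior(man$apex_um, man$c1sq_um2, man$c2sq_um2,
                               man$tilt_deg, d, 0.25)
  expect_identical(apexquant:::.paraboloidInterior(p, d, 0.25), oracle)
  masked <- applyMask(iso, p, "rep")
  expected <- getChannel(iso, "rep")
  expected[!oracle] <- 0
  expect_identical(getChannel(masked, "rep"), expected)
  # surviving intensity of a uniform channel = v * interior voxel count
  ones <- VoxelStack(list(u = array(1, d)), voxelSizeXY = 0.25,
                     voxelSizeZ = 0.25)
  mOnes <- applyMask(resampleIsotropic(ones), p, "u")
  expect_equal(sum(getChannel(mOnes, "u")), sum(oracle))
})

test_that("mask edge cases behave as documented", {
  d <- c(10, 12, 12)
  ones <- resampleIsotropic(
    VoxelStack(list(u = array(1, d)), voxelSizeXY = 0.5, voxelSizeZ = 0.5))
  # paraboloid covering the whole grid: stack unchanged
  pBig <- new("Paraboloid3D", apex = c(3, 3, -50), c1sq = 1e6, c2sq = 1e6,
              theta = 0, lateralComplete = TRUE)
  expect_identical(getChannel(applyMask(ones, pBig, "u"), "u"),
                   getChannel(ones, "u"))
  # apex below the deepest slice: all-zero channel with a warning
  pDeep <- new("Paraboloid3D", apex = c(3, 3, 100), c1sq = 20, c2sq = 20,
               theta = 0, lateralComplete = TRUE)
  expect_warning(mz <- applyMask(ones, pDeep, "u"), "deepest slice")
  expect_true(all(getChannel(mz, "u") == 0))
})

test_that("masked intensity never increases under inflation", {
  g <- smallDome(value = 50, seed = 31)
  iso <- asIso(g$stack)
  man <- g$manifest
  p <- new("Paraboloid3D", apex = man$apex_um, c1sq = man$c1sq_um2,
           c2sq = man$c2sq_um2, theta = 0, lateralComplete = TRUE)
  tots <- vapply(c(0.9, 0.6, 0.3), function(al)
    sum(getChannel(applyMask(iso, inflateCurvature(p, al), "rep"),
                   "rep")), 0)
  expect_true(all(diff(tots) <= 0))
  expect_lte(tots[1L], sum(getChannel(applyMask(iso, p, "rep"), "rep")))
})
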