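test_that("cropping keeps the requested window and all slices", {
  a <- array(runif(8 * 10 * 12), c(8, 10, 12))
  st <- VoxelStack(list(c1 = a), voxelSizeXY = 0.4, voxelSizeZ = 0.4)
  full <- cropSubstack(st, c(1, 12, 1, 10))
  expect_identical(getChannel(full, "c1"), a)
  sub <- cropSubstack(st, c(2, 11, 3, 12 - 4))
  expect_equal(dim(sub), c(8L, 6L, 10L))
  expect_identical(getChannel(sub, "c1"), a[, 3:8, 2:11])
  expect_error(cropSubstack(st, c(5, 4, 1, 10)), "empty")
  expect_error(cropSubstack(st, c(1, 13, 1, 10)), "outside")
})

test_that("cropping excludes an off-centre blob from the projections", {
  g <- gaussianDomainStack(sigmaUm = c(4, 4, 3), dim = c(48, 96, 96))
  st <- g$stack
  # blob is centred in the grid; crop a corner away from it
  corner <- cropSubstack(st, c(1, 20, 1, 20))
  pr <- orthogonalProjections(resampleIsotropic(corner), "domain")
  full <- orthogonalProjections(resampleIsotropic(st), "domain")
  expect_lt(sum(pr$xz@pixels), 1e-6 * sum(full$xz@pixels))
})

test_that("orthogonal projections conserve intensity and separate blobs", {
  d <- c(10, 20, 20)
  a <- array(0, d)
  a[4, 7, 12] <- 5
  st <- VoxelStack(list(c1 = a), voxelSizeXY = 0.5, voxelSizeZ = 0.5)
  pr <- orthogonalProjections(st, "c1")
  expect_equal(sum(pr$xz@pixels == 5), 1L)
  expect_equal(pr$xz@pixels[4, 12], 5)
  expect_equal(pr$yz@pixels[4, 7], 5)
  expect_equal(sum(pr$xz@pixels), sum(a))
  expect_equal(sum(pr$yz@pixels), sum(a))
  # two blobs sharing (x, z) but differing in y merge in xz, split in yz
  b <- array(0, d)
  b[5, 5, 10] <- 1; b[5, 15, 10] <- 1
  stb <- VoxelStack(list(c1 = b), voxelSizeXY = 0.5, voxelSizeZ = 0.5)
  prb <- orthogonalProjections(stb, "c1")
  expect_equal(sum(prb$xz@pixels > 0), 1L)   # merged
  expect_equal(sum(prb$yz@pixels > 0), 2L)   # separated
})

test_that("the half-maximum ellipse of a Gaussian has the analytic width", {
  fwhmFactor <- 2 * sqrt(2 * log(2))
  for (sg in c(6, 8)) {
    g <- gaussianDomainStack(sigmaUm = c(sg, sg * 0.75, 5))
    pr <- orthogonalProjections(asIso(g$stack), "domain")
    e <- isoclineEllipse(pr$xz)
    expect_lt(abs(domainWidth(e) - fwhmFactor * sg) / (fwhmFactor * sg),
              0.05)
    expect_lt(abs(domainHeight(e) - fwhmFactor * 5) / (fwhmFactor * 5),
              0.05)
  }
})

test_that("an isotropic Gaussian yields a circle and scaling changes
           nothing", {
  g <- gaussianDomainStack(sigmaUm = c(6, 6, 6))
  pr <- orthogonalProjections(asIso(g$stack), "domain")
  e <- isoclineEllipse(pr$xz)
  expect_lt(abs(domainHeight(e) - domainWidth(e)) / domainWidth(e), 0.02)
  # threshold is relative: doubling intensities leaves the ellipse alone
  pr2 <- pr$xz
  pr2@pixels <- pr2@pixels * 2
  e2 <- isoclineEllipse(pr2)
  expect_equal(domainHeight(e2), domainHeight(e), tolerance = 1e-9)
  expect_equal(domainWidth(e2), domainWidth(e), tolerance = 1e-9)
  expect_equal(e2@center, e@center, tolerance = 1e-9)
})

test_that("the recovered axis converges to 2 sigma sqrt(2 ln 2) with
           finer pixels", {
  fwhm <- 2 * sqrt(2 * log(2)) * 6
  errAt <- function(vx, dm) {
    g <- gaussianDomainStack(sigmaUm = c(6, 6, 6), voxel = vx, dim = dm)
    e <- isoclineEllipse(orthogonalProjections(asIso(g$stack),
                                               "domain")$xz)
    abs(domainWidth(e) - fwhm) / fwhm
  }
  eCoarse <- errAt(1, c(40, 64, 64))
  eFine <- errAt(0.5, c(72, 120, 120))
  expect_lt(eFine, eCoarse + 1e-9)
  expect_lt(eFine, 0.03)
})

test_that("border-touching isoclines are flagged, not fitted", {
  g <- gaussianDomainStack(sigmaUm = c(30, 30, 5), dim = c(48, 64, 64))
  pr <- orthogonalProjections(asIso(g$stack), "domain")
  expect_error(isoclineEllipse(pr$xz), "border")
  zero <- pr$xz
  zero@pixels <- zero@pixels * 0
  expect_error(isoclineEllipse(zero), "no positive signal")
})

test_that("the two side views are averaged into one height and width", {
  mk <- function(h, w, plane)
    new("DomainEllipse", center = c(0, 0), heightUm = h, widthUm = w,
        orientationDeg = 0, fraction = 0.5, plane = plane,
        nContour = 10L, method = "conic")
  same <- domainDimensions(mk(20, 30, "xz"), mk(20, 30, "yz"))
  expect_equal(same$height_um, 20)
  expect_equal(same$width_um, 30)
  mix <- domainDimensions(mk(20, 28, "xz"), mk(22, 32, "yz"))
  expect_equal(mix$height_um, 21)
  expect_equal(mix$width_um, 30)
  expect_equal(nrow(mix$per_view), 2L)
})

test_that("periphery metrics are exact arithmetic on valid pairs", {
  one <- peripheryMetrics(100, 40)
  expect_equal(one$periphery_um, 30)
  expect_equal(one$pz_oc_ratio, 0.75)
  expect_equal(peripheryMetrics(55, 55)$periphery_um, 0)
  set.seed(4)
  W <- runif(1000, 40, 150)
  woc <- runif(1000, 1, 1) * W * runif(1000, 0.2, 1)
  tab <- peripheryMetrics(W, woc)
  expect_equal(tab$periphery_um, (W - woc) / 2)
  expect_equal(tab$pz_oc_ratio, (W - woc) / 2 / woc)
  expect_error(peripheryMetrics(50, 60), "meristem width")
  expect_error(peripheryMetrics(50, 0), "undefined")
})
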