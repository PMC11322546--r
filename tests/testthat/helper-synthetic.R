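# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# A small isotropic dome stack (voxel 0.25 um) with a uniform reporter.
smallDome <- function(value = 100, background = 0, tiltDeg = 0,
                      seed = 11, noise = FALSE) {
  dome <- domeSpec(apexUm = c(6.3, 6.3, 1.1),
                   curvatures = c(0.0513, 0.0627), tiltDeg = tiltDeg)
  rp <- reporterSpec("rep", value = value, background = background,
                     poissonGain = if (noise) 1 else 0,
                     readSd = if (noise) 2 else 0)
  makeDomeStack(dome, list(rp), dim = c(48, 52, 52),
                voxelSizes = c(0.25, 0.25), seed = seed)
}

asIso <- function(stack) resampleIsotropic(stack)

# Independent brute-force interior oracle: per-slice scalar evaluation of
# the paraboloid inequality, structured differently from the package's
# vectorised path.
bruteForceInterior <- function(apex, c1sq, c2sq, thetaDeg, dimZYX,
                               voxelSize) {
  th <- thetaDeg * pi / 180
  out <- array(FALSE, dimZYX)
  ys <- (seq_len(dimZYX[2L]) - 1) * voxelSize
  xs <- (seq_len(dimZYX[3L]) - 1) * voxelSize
  for (iz in seq_len(dimZYX[1L])) {
    dz <- (iz - 1) * voxelSize - apex[3L]
    for (ix in seq_along(xs)) {
      dx <- xs[ix] - apex[1L]
      xr <- cos(th) * dx + sin(th) * dz
      zr <- -sin(th) * dx + cos(th) * dz
      rem <- zr - xr * xr / c1sq
      # interior in y wherever (y - y0)^2 <= rem * c2sq
      if (rem >= 0) {
        half <- sqrt(rem * c2sq)
        out[iz, abs(ys - apex[2L]) <= half, ix] <- TRUE
      }
    }
  }
  out
}

# A 3D Gaussian blob inside a near-flat dome, for isocline tests.
gaussianDomainStack <- function(sigmaUm = c(8, 8, 5), voxel = 0.5,
                                dim = c(72, 120, 120), amplitude = 500,
                                seed = 3) {
  ext <- c((dim[3L] - 1) * voxel, (dim[2L] - 1) * voxel,
           (dim[1L] - 1) * voxel)
  ctr <- c(ext[1L] / 2, ext[2L] / 2, ext[3L] / 2)
  dome <- domeSpec(apexUm = c(ctr[1L], ctr[2L], 0.01),
                   curvatures = c(1e-4, 1e-4))
  rp <- reporterSpec("domain", mode = "nuclear-gaussian",
                     centerUm = ctr, sigmaUm = sigmaUm,
                     amplitude = amplitude)
  makeDomeStack(dome, list(rp), dim = dim, voxelSizes = c(voxel, voxel),
                seed = seed)
}
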