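#' @include stack-io.R
NULL

#' Specify a synthetic meristem dome
#'
#' @param apexUm apex position (x0, y0, z0), micrometres.
#' @param curvatures (a1, a2) of the surface
#'   \code{z = z0 + a1 (x - x0)^2 + a2 (y - y0)^2}, 1/micrometres.
#' @param tiltDeg rigid rotation of the surface about the y axis through
#'   the apex, degrees.
#' @param wallThicknessUm Gaussian sd of the cell-wall shell, micrometres.
#' @param wallAmplitude peak wall-channel intensity.
#' @param primordia optional list of lateral bumps (see
#'   [DomeSpec-class]).
#' @return a [DomeSpec-class]
#' @export
domeSpec <- function(apexUm, curvatures, tiltDeg = 0,
                     wallThicknessUm = 1, wallAmplitude = 200,
                     primordia = list()) {
  new("DomeSpec", apexUm = apexUm, curvatures = curvatures,
      tiltDeg = tiltDeg, wallThicknessUm = wallThicknessUm,
      wallAmplitude = wallAmplitude, primordia = primordia)
}

#' Specify a synthetic reporter channel
#'
#' @param name channel name.
#' @param mode "uniform-interior", "graded" or "nuclear-gaussian".
#' @param value interior value for uniform/graded modes (a.u.).
#' @param gradeLengthUm linear decay depth for graded mode, micrometres.
#' @param centerUm,sigmaUm,amplitude 3D Gaussian parameters for
#'   nuclear-gaussian mode (micrometres / a.u.).
#' @param background constant offset added everywhere.
#' @param poissonGain Poisson shot-noise gain (0 = noiseless).
#' @param readSd Gaussian read-noise sd (0 = none).
#' @return a [ReporterSpec-class]
#' @export
reporterSpec <- function(name, mode = "uniform-interior", value = 100,
                         gradeLengthUm = 30, centerUm = c(0, 0, 0),
                         sigmaUm = c(5, 5, 5), amplitude = 100,
                         background = 0, poissonGain = 0, readSd = 0) {
  new("ReporterSpec", name = name, mode = mode, value = value,
      gradeLengthUm = gradeLengthUm, centerUm = centerUm,
      sigmaUm = sigmaUm, amplitude = amplitude, background = background,
      poissonGain = poissonGain, readSd = readSd)
}

# Apex-relative rotated-frame fields shared by the generator and the
# interior oracle: returns the (nz, nx) matrices of rotated lateral and
# axial offsets for the (x, z) plane, given physical axis coordinates.
.tiltFields <- function(xs, zs, apexXZ, tiltDeg) {
  th <- tiltDeg * pi / 180
  dx <- xs - apexXZ[1L]
  dz <- zs - apexXZ[2L]
  # R(-theta) applied to (dx, dz); outer over (z, x)
  xr <- outer(dz, dx, function(z, x) cos(th) * x + sin(th) * z)
  zr <- outer(dz, dx, function(z, x) -sin(th) * x + cos(th) * z)
  list(xr = xr, zr = zr)
}

# Interior membership and depth-below-surface for a dome on a grid.
# Returns list(interior = logical (z,y,x), depth = numeric (z,y,x)).
.domeInterior <- function(dome, dimZYX, voxelSizeXY, voxelSizeZ) {
  nz <- dimZYX[1L]; ny <- dimZYX[2L]; nx <- dimZYX[3L]
  xs <- .axisCoords(nx, voxelSizeXY)
  ys <- .axisCoords(ny, voxelSizeXY)
  zs <- .axisCoords(nz, voxelSizeZ)
  f <- .tiltFields(xs, zs, dome@apexUm[c(1L, 3L)], dome@tiltDeg)
  a <- dome@curvatures
  dy2 <- (ys - dome@apexUm[2L])^2
  # depth[z,y,x] = zr - a1*xr^2 - a2*dy^2 (+ primordium bumps)
  B <- f$zr - a[1L] * f$xr^2                    # (nz, nx)
  depth <- aperm(outer(B, a[2L] * dy2, `-`), c(1L, 3L, 2L))
  for (p in dome@primordia) {
    g1 <- p$amplitudeUm *
      exp(-(f$xr - p$offsetUm[1L])^2 / (2 * p$sigmaUm^2))   # (nz, nx)
    g2 <- exp(-((ys - dome@apexUm[2L]) - p$offsetUm[2L])^2 /
                (2 * p$sigmaUm^2))                           # (ny)
    depth <- depth + aperm(outer(g1, g2), c(1L, 3L, 2L))
  }
  list(interior = depth >= 0, depth = depth)
}

#' Generate a confocal-like dome stack with known ground truth
#'
#' Channel 1 (\code{"wall"}) is a Gaussian shell around the (possibly
#' tilted) paraboloid surface of \code{dome}; each further channel follows
#' its [ReporterSpec-class], restricted to the tissue interior (at or
#' below the surface). The returned manifest records every ground-truth
#' quantity a downstream estimator could be scored against: dome
#' parameters, per-channel truth, interior voxel count, and (for untilted
#' domes) morphometric landmarks at the deepest fully-contained plane.
#'
#' @param dome a [DomeSpec-class]; the apex must lie inside the grid.
#' @param reporters list of [ReporterSpec-class] objects (may be empty).
#' @param dim grid shape \code{c(nz, ny, nx)}.
#' @param voxelSizes numeric(2) \code{c(xy, z)} micrometres; the default
#'   0.2/0.4 mirrors routine acquisition anisotropy.
#' @param seed integer RNG seed (mandatory: generators are pure functions
#'   of spec and seed).
#' @return list with elements \code{stack} (a [VoxelStack-class]) and
#'   \code{manifest} (a list).
#' @export
makeDomeStack <- function(dome, reporters = list(),
                          dim = c(96, 128, 128),
                          voxelSizes = c(0.2, 0.4), seed) {
  stopifnot(is(dome, "DomeSpec"), !missing(seed))
  if (any(dim < 1L)) stop("zero-size grid")
  ext <- c((dim[3L] - 1) * voxelSizes[1L], (dim[2L] - 1) * voxelSizes[1L],
           (dim[1L] - 1) * voxelSizes[2L])
  if (any(dome@apexUm < 0) || any(dome@apexUm > ext))
    stop("dome apex outside grid")
  set.seed(seed)
  geo <- .domeInterior(dome, dim, voxelSizes[1L], voxelSizes[2L])
  wall <- dome@wallAmplitude *
    exp(-geo$depth^2 / (2 * dome@wallThicknessUm^2))
  ints <- list(wall = wall)
  truths <- list()
  xs <- .axisCoords(dim[3L], voxelSizes[1L])
  ys <- .axisCoords(dim[2L], voxelSizes[1L])
  zs <- .axisCoords(dim[1L], voxelSizes[2L])
  for (rp in reporters) {
    ch <- switch(rp@mode,
      "uniform-interior" = rp@value * geo$interior,
      "graded" = rp@value * pmax(0, 1 - geo$depth / rp@gradeLengthUm) *
        geo$interior,
      "nuclear-gaussian" = {
        gz <- exp(-(zs - rp@centerUm[3L])^2 / (2 * rp@sigmaUm[3L]^2))
        gy <- exp(-(ys - rp@centerUm[2L])^2 / (2 * rp@sigmaUm[2L]^2))
        gx <- exp(-(xs - rp@centerUm[1L])^2 / (2 * rp@sigmaUm[1L]^2))
        rp@amplitude * (gz %o% gy %o% gx) * geo$interior
      })
    ch <- ch + rp@background
    if (rp@poissonGain > 0)
      ch <- array(rp@poissonGain *
                    stats::rpois(length(ch), ch / rp@poissonGain), dim(ch))
    if (rp@readSd > 0)
      ch <- ch + array(stats::rnorm(length(ch), sd = rp@readSd), dim(ch))
    ints[[rp@name]] <- pmax(ch, 0)
    truths[[rp@name]] <- list(
      mode = rp@mode, value = rp@value, amplitude = rp@amplitude,
      background = rp@background, centerUm = rp@centerUm,
      sigmaUm = rp@sigmaUm, poissonGain = rp@poissonGain,
      readSd = rp@readSd)
  }
  # morphometric landmarks (untilted domes): width at the deepest plane
  # fully contained in the grid below the apex
  landmarks <- NULL
  if (dome@tiltDeg == 0) {
    hBase <- ext[3L] - dome@apexUm[3L]
    wBase <- 2 * sqrt(hBase / dome@curvatures[1L])
    landmarks <- list(
      height_um = hBase, width_um = wBase,
      apex = c(dome@apexUm[1L], dome@apexUm[3L]),
      end1 = c(dome@apexUm[1L] - wBase / 2, dome@apexUm[3L] + hBase),
      end2 = c(dome@apexUm[1L] + wBase / 2, dome@apexUm[3L] + hBase))
  }
  manifest <- list(
    seed = seed, dim_zyx = dim,
    voxel_size_xy_um = voxelSizes[1L], voxel_size_z_um = voxelSizes[2L],
    apex_um = dome@apexUm, curvatures = dome@curvatures,
    c1sq_um2 = 1 / dome@curvatures[1L], c2sq_um2 = 1 / dome@curvatures[2L],
    tilt_deg = dome@tiltDeg, wall_thickness_um = dome@wallThicknessUm,
    interior_voxels = sum(geo$interior),
    reporters = truths, landmarks = landmarks)
  list(stack = VoxelStack(ints, voxelSizeXY = voxelSizes[1L],
                          voxelSizeZ = voxelSizes[2L]),
       manifest = manifest)
}

#' Sample noisy points on a rotated parabola
#'
#' Points lie on the curve \code{apex + R(tilt) \%*\% (u, a u^2)} for
#' \code{n} values of \code{u} spanning \code{[-halfSpanUm, halfSpanUm]},
#' with isotropic Gaussian jitter of sd \code{noiseSd}. This is the
#' reproducible stand-in for the hand-drawn outline step of the mask
#' pipeline.
#'
#' @param apexUm numeric(2) apex (u0, w0), micrometres.
#' @param curvature parabola coefficient a, 1/micrometres.
#' @param tiltDeg frame rotation, degrees.
#' @param n number of points (>= 3).
#' @param noiseSd jitter sd, micrometres.
#' @param seed RNG seed.
#' @param halfSpanUm half-range of the lateral parameter.
#' @return n x 2 matrix of (u, w) points in micrometres.
#' @export
makeOutlinePoints <- function(apexUm, curvature, tiltDeg = 0, n = 50,
                              noiseSd = 0, seed = 1, halfSpanUm = 20) {
  if (n < 3L) stop("need at least 3 outline points")
  set.seed(seed)
  u <- seq(-halfSpanUm, halfSpanUm, length.out = n)
  pts <- cbind(u, curvature * u^2) %*% t(.rot2(tiltDeg))
  pts <- sweep(pts, 2L, apexUm, `+`)
  if (noiseSd > 0) pts <- pts + matrix(stats::rnorm(2L * n, sd = noiseSd),
                                       ncol = 2L)
  colnames(pts) <- c("u_um", "w_um")
  pts
}

#' Generate a per-cell area table with known meristem total
#'
#' Stand-in for a segmentation export: lognormal cell areas plus a
#' Bernoulli meristem-membership flag (membership itself is decided by
#' curvature criteria in the external segmentation tool, so here it is
#' simply drawn at the requested rate).
#'
#' @param nCells number of cells (>= 1).
#' @param meanAreaUm2 median cell area, square micrometres.
#' @param sdlog lognormal dispersion of areas (0 = all equal).
#' @param meristemFraction probability a cell belongs to the meristem.
#' @param seed RNG seed.
#' @return list with \code{cells} (data.frame \code{area_um2},
#'   \code{meristem_member}) and \code{manifest} (total meristem area and
#'   member count).
#' @export
makeCellTable <- function(nCells, meanAreaUm2 = 25, sdlog = 0.25,
                          meristemFraction = 1, seed = 1) {
  if (nCells < 1L) stop("need at least one cell")
  set.seed(seed)
  areas <- if (sdlog > 0)
    stats::rlnorm(nCells, meanlog = log(meanAreaUm2), sdlog = sdlog)
  else rep(meanAreaUm2, nCells)
  member <- stats::runif(nCells) < meristemFraction
  cells <- data.frame(area_um2 = areas, meristem_member = member)
  list(cells = cells,
       manifest = list(total_meristem_area_um2 = sum(areas[member]),
                       member_cells = sum(member), seed = seed))
}

#' Default cohort design for a synthetic floral-transition timecourse
#'
#' Median trajectories anchored to the reported morphometric dynamics:
#' wild-type height doubles (45 to 90 um) and width increases 1.5-fold
#' (70 to 105 um) from the first to the peak timepoint, while the mutant
#' genotype plateaus and at the peak timepoint is 50% smaller in height
#' and 25% smaller in width than wild type.
#'
#' @param genotypes names for the two genotypes.
#' @param timepoints sampling days.
#' @param n plants per genotype and timepoint.
#' @return design data.frame consumed by [makeTimecourse()]
#' @export
defaultCohortDesign <- function(genotypes = c("wild-type", "mutant"),
                                timepoints = c(10, 12, 14), n = 8) {
  wt <- data.frame(
    genotype = genotypes[1L], timepoint_d = timepoints,
    median_height_um = c(45, 67.5, 90),
    median_width_um = c(70, 87.5, 105),
    median_area_um2 = c(4000, 6000, 9000),
    primordium_identity = c("vegetative", "cauline", "cauline"),
    n = n)
  mut <- data.frame(
    genotype = genotypes[2L], timepoint_d = timepoints,
    median_height_um = c(45, 50, 45),
    median_width_um = c(70, 75, 78.75),
    median_area_um2 = c(4000, 4500, 4500),
    primordium_identity = c("vegetative", "cauline", "floral"),
    n = n)
  rbind(wt, mut)
}

#' Draw a synthetic morphometric timecourse
#'
#' Each design row contributes \code{n} meristems whose height, width and
#' area are drawn lognormally around the row medians with common
#' dispersion \code{sdlog} (the median of the generating distribution
#' equals the design median exactly; \code{sdlog = 0} collapses to the
#' medians).
#'
#' @param design data.frame as produced by [defaultCohortDesign()].
#' @param sdlog lognormal dispersion of all measures.
#' @param experimentId experiment label stored in each record.
#' @param seed RNG seed.
#' @return a morphometric record data.frame (schema of [writeTable()]
#'   \code{what = "morph"}).
#' @export
makeTimecourse <- function(design, sdlog = 0.1, experimentId = "sim1",
                           seed = 1) {
  need <- c("genotype", "timepoint_d", "median_height_um",
            "median_width_um", "n")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(design$median_height_um <= 0 | design$median_width_um <= 0))
    stop("design medians must be positive")
  set.seed(seed)
  draw <- function(m, n) if (sdlog > 0)
    stats::rlnorm(n, meanlog = log(m), sdlog = sdlog) else rep(m, n)
  out <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    r <- design[i, ]
    data.frame(
      genotype = r$genotype, timepoint_d = r$timepoint_d,
      height_um = draw(r$median_height_um, r$n),
      width_um = draw(r$median_width_um, r$n),
      area_um2 = if ("median_area_um2" %in% names(r))
        draw(r$median_area_um2, r$n) else NA_real_,
      primordium_identity = if ("primordium_identity" %in% names(r))
        r$primordium_identity else "vegetative",
      experiment_id = experimentId)
  }))
  rownames(out) <- NULL
  .checkMorphRecords(out)
}
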