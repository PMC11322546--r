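#' @include paraboloid-mask.R
NULL

#' Depth-limited upper region of a paraboloid on a voxel grid
#'
#' Interior voxels whose axial distance from the apex, measured along the
#' (possibly tilted) paraboloid axis, is at most \code{depthUm}: the
#' region between the paraboloid surface and a transversal plane cut
#' perpendicular to the paraboloid axis at that depth. Routine
#' quantification uses 20 or 50 micrometres.
#'
#' @param p a [Paraboloid3D-class]
#' @param dim grid shape \code{c(nz, ny, nx)}
#' @param voxelSize isotropic voxel size, micrometres
#' @param depthUm depth limit below the apex, micrometres (> 0)
#' @return a [MaskRegion-class]
#' @export
upperRegion <- function(p, dim, voxelSize, depthUm) {
  stopifnot(is(p, "Paraboloid3D"), depthUm > 0, voxelSize > 0)
  xs <- .axisCoords(dim[3L], voxelSize)
  ys <- .axisCoords(dim[2L], voxelSize)
  zs <- .axisCoords(dim[1L], voxelSize)
  f <- .tiltFields(xs, zs, p@apex[c(1L, 3L)], p@theta)
  B <- f$zr - f$xr^2 / p@c1sq
  dy2 <- (ys - p@apex[2L])^2 / p@c2sq
  interior <- aperm(outer(B, dy2, `-`), c(1L, 3L, 2L)) >= 0
  withinDepth <- aperm(outer(f$zr <= depthUm, rep(TRUE, dim[2L]), `&`),
                       c(1L, 3L, 2L))
  m <- interior & withinDepth
  if (!any(m)) stop("empty region: paraboloid does not intersect the grid")
  new("MaskRegion", mask = m, depthUm = depthUm, voxelSize = voxelSize,
      paraboloid = p)
}

#' Gaussian smoothing restricted to the paraboloid interior
#'
#' Applies a renormalised (mask-weighted) Gaussian filter to one channel
#' inside the paraboloid: within the mask the result is
#' \code{conv(I * M) / conv(M)}, so voxels near the mask boundary are not
#' diluted by the zeroed exterior; voxels outside are untouched. The
#' default \code{sigma = 2.5} pixels matches the setting used for diffuse
#' GFP-fusion quantification.
#'
#' @param stack an [IsotropicStack-class]
#' @param region a [MaskRegion-class] or [Paraboloid3D-class] (for a
#'   paraboloid the full interior on the stack grid is used)
#' @param sigma Gaussian sd in pixels (> 0)
#' @param channel channel to smooth
#' @return the stack with the channel smoothed in-region
#' @export
smoothInRegion <- function(stack, region, sigma = 2.5, channel) {
  stopifnot(is(stack, "VoxelStack"), sigma > 0)
  if (!isIsotropic(stack)) stop("smoothInRegion requires an isotropic stack")
  m <- if (is(region, "MaskRegion")) region@mask
       else .paraboloidInterior(region, dim(stack), stack@voxelSizeXY)
  a <- getChannel(stack, channel)
  stack@intensities[[channel]] <- .gaussSmoothMasked(a, m, sigma)
  stack
}

#' Fluorescence concentration in a mask region
#'
#' The concentration proxy: total intensity (sum of voxel intensities in
#' the region) divided by total volume (member voxel count times the
#' voxel volume). The reported value is additionally divided by 1000 for
#' display on the customary scale.
#'
#' @param stack an [IsotropicStack-class]; raw anisotropic stacks are
#'   refused (resample first, so the per-voxel volume is well defined).
#' @param region a non-empty [MaskRegion-class] on the same grid
#' @param channel reporter channel to measure
#' @param sigma smoothing sigma (pixels) already applied in-region, for
#'   the record; \code{NA} when none was
#' @return a [FluorMeasure-class]
#' @export
concentration <- function(stack, region, channel, sigma = NA_real_) {
  stopifnot(is(stack, "VoxelStack"), is(region, "MaskRegion"))
  if (!isIsotropic(stack))
    stop("concentration requires an isotropic stack; resample first")
  if (!identical(dim(stack), dim(region@mask)))
    stop("region grid does not match the stack grid")
  if (!isTRUE(all.equal(stack@voxelSizeXY, region@voxelSize)))
    stop("region voxel size does not match the stack")
  n <- sum(region@mask)
  if (n == 0L) stop("empty region")
  tot <- sum(getChannel(stack, channel)[region@mask])
  vol <- n * region@voxelSize^3
  conc <- tot / vol
  new("FluorMeasure", totalIntensity = tot, volumeUm3 = vol,
      concentration = conc, reportedConcentration = conc / 1000,
      sigma = sigma, depthUm = region@depthUm, channel = channel)
}

#' One-call reporter quantification
#'
#' Convenience wrapper for the routine sequence: optionally inflate the
#' paraboloid curvature by \code{alpha}, mask the reporter channel,
#' optionally smooth inside the paraboloid (for diffuse GFP-fusion-like
#' profiles), take the depth-limited upper region and measure the
#' concentration.
#'
#' @param stack an [IsotropicStack-class]
#' @param p a [Paraboloid3D-class]
#' @param channel reporter channel
#' @param depthUm quantification depth, micrometres (20 or 50 in routine
#'   use)
#' @param sigmaPx in-region Gaussian smoothing sd in pixels, or \code{NA}
#'   to skip
#' @param alpha curvature inflation factor in (0, 1), or \code{NULL} to
#'   skip inflation
#' @return a [FluorMeasure-class]
#' @export
quantifyReporter <- function(stack, p, channel, depthUm = 50,
                             sigmaPx = NA_real_, alpha = NULL) {
  if (!is.null(alpha)) p <- inflateCurvature(p, alpha)
  stack <- applyMask(stack, p, channel)
  if (!is.na(sigmaPx))
    stack <- smoothInRegion(stack, p, sigma = sigmaPx, channel = channel)
  region <- upperRegion(p, dim(stack), stack@voxelSizeXY, depthUm)
  concentration(stack, region, channel, sigma = sigmaPx)
}

#' @rdname measure-accessors
#' @export
concentrationValue <- function(x) x@concentration
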