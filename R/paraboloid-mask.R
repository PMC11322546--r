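#' @include synthetic.R
NULL

#' Sum projection of one channel onto an orthogonal side-view plane
#'
#' Collapses the out-of-plane lateral axis (y for plane "xz", x for
#' "yz") by summing, restricted to an interval of slices along that axis
#' that should contain the meristem apex. The default interval is the
#' central half of the collapsed axis. Rows of the result index depth
#' (z), columns the retained lateral axis.
#'
#' @param stack an [IsotropicStack-class] (projections feeding the mask
#'   fit are taken after resampling so pixels are square).
#' @param channel channel to project (default the wall channel).
#' @param plane "xz" or "yz".
#' @param sliceInterval 1-based \code{c(from, to)} interval on the
#'   collapsed axis; \code{NULL} for the central half.
#' @return a [ProjectionImage-class]
#' @export
sumProjection <- function(stack, channel = "wall", plane = c("xz", "yz"),
                          sliceInterval = NULL) {
  plane <- match.arg(plane)
  stopifnot(is(stack, "VoxelStack"))
  if (!isIsotropic(stack))
    stop("projections for mask fitting require an isotropic stack")
  a <- getChannel(stack, channel)
  d <- dim(a)
  nCollapse <- if (plane == "xz") d[2L] else d[3L]
  if (is.null(sliceInterval))
    sliceInterval <- c(floor(nCollapse / 4) + 1L,
                       nCollapse - floor(nCollapse / 4))
  si <- as.integer(sliceInterval)
  if (si[1L] > si[2L] || si[1L] < 1L || si[2L] > nCollapse)
    stop("slice interval out of bounds or empty")
  px <- if (plane == "xz") {
    apply(a[, si[1L]:si[2L], , drop = FALSE], c(1L, 3L), sum)
  } else {
    apply(a[, , si[1L]:si[2L], drop = FALSE], c(1L, 2L), sum)
  }
  new("ProjectionImage", pixels = px, plane = plane,
      pixelSize = stack@voxelSizeXY, sliceInterval = as.numeric(si))
}

# Quadratic least-squares in a frame rotated by -thetaDeg; returns fit
# summary or NULL when degenerate (non-positive curvature).
.fitParabolaAt <- function(points, thetaDeg) {
  pr <- points %*% t(.rot2(-thetaDeg))
  u <- pr[, 1L]; w <- pr[, 2L]
  X <- cbind(1, u, u * u)
  fit <- tryCatch(stats::lm.fit(X, w), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
  cf <- fit$coefficients
  a <- cf[[3L]]
  if (!is.finite(a) || a <= 0) return(NULL)
  rss <- sum(fit$residuals^2)
  list(a = a, c0 = cf[[1L]], c1 = cf[[2L]], rss = rss,
       tss = sum((w - mean(w))^2))
}

#' Fit a tilted parabola to outline points
#'
#' Searches orientations over \code{thetaRange}: for each candidate the
#' points are rotated into the candidate frame and a quadratic
#' \code{w = w0 + a (u - u0)^2} is fitted by least squares; the
#' orientation minimising the residual sum of squares wins (coarse grid
#' then golden-section refinement to ~0.05 degrees). The apex is reported
#' in the unrotated frame.
#'
#' @param points n x 2 matrix of (u, w) micrometre points, n >= 3,
#'   non-collinear.
#' @param thetaRange degrees, default \code{c(-20, 20)}.
#' @param coarseStepDeg coarse grid step, degrees.
#' @return a [Parabola2D-class]
#' @export
fitParabola <- function(points, thetaRange = c(-20, 20),
                        coarseStepDeg = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 outline points")
  if (qr(cbind(1, points))$rank < 3L)
    stop("outline points are collinear")
  grid <- seq(thetaRange[1L], thetaRange[2L], by = coarseStepDeg)
  rssAt <- function(th) {
    f <- .fitParabolaAt(points, th)
    if (is.null(f)) Inf else f$rss
  }
  rssGrid <- vapply(grid, rssAt, 0)
  if (all(!is.finite(rssGrid)))
    stop("all candidate fits degenerate (non-positive curvature)")
  best <- grid[which.min(rssGrid)]
  lo <- max(thetaRange[1L], best - coarseStepDeg)
  hi <- min(thetaRange[2L], best + coarseStepDeg)
  thetaHat <- best
  if (hi > lo) {
    opt <- stats::optimize(rssAt, c(lo, hi), tol = 0.025)
    if (opt$objective <= min(rssGrid)) thetaHat <- opt$minimum
  }
  f <- .fitParabolaAt(points, thetaHat)
  u0r <- -f$c1 / (2 * f$a)
  w0r <- f$c0 - f$c1^2 / (4 * f$a)
  apex <- as.numeric(.rot2(thetaHat) %*% c(u0r, w0r))
  gof <- if (f$tss > 0) 1 - f$rss / f$tss else 1
  new("Parabola2D", apex = apex, curvature = f$a, theta = thetaHat,
      rss = f$rss, gof = gof)
}

#' Assemble the 3D paraboloid from the orthogonal parabola fits
#'
#' The surface (in the tilt-rotated frame, apex-relative) is
#' \code{z = x^2 / c1sq + y^2 / c2sq} with \code{c1sq = 1 / a_xz} and
#' \code{c2sq = 1 / a_yz}, so that it matches the quadratic term of each
#' 2D fit in its own plane. The apex depth is the mean of the two
#' parabola apex depths. When the lateral (yz) view is incomplete the xz
#' curvature is reused (\code{c2sq = c1sq}) and the apex y must be
#' supplied.
#'
#' @param pXZ [Parabola2D-class] from the xz view (u = x, w = z).
#' @param pYZ [Parabola2D-class] from the yz view (u = y, w = z), or
#'   \code{NULL} when the lateral view is unusable.
#' @param y0 apex y (micrometres), required when \code{pYZ} is NULL.
#' @return a [Paraboloid3D-class]; its tilt is the xz-view orientation.
#' @export
buildParaboloid <- function(pXZ, pYZ = NULL, y0 = NULL) {
  stopifnot(is(pXZ, "Parabola2D"))
  lateral <- !is.null(pYZ)
  if (lateral) {
    stopifnot(is(pYZ, "Parabola2D"))
    z0 <- mean(c(pXZ@apex[2L], pYZ@apex[2L]))
    yApex <- pYZ@apex[1L]
    c2 <- 1 / pYZ@curvature
  } else {
    if (is.null(y0)) stop("y0 is required when the lateral view is missing")
    z0 <- pXZ@apex[2L]
    yApex <- y0
    c2 <- 1 / pXZ@curvature
  }
  new("Paraboloid3D", apex = c(pXZ@apex[1L], yApex, z0),
      c1sq = 1 / pXZ@curvature, c2sq = c2, theta = pXZ@theta,
      lateralComplete = lateral)
}

#' Inflate the paraboloid curvature to exclude boundary signal
#'
#' Replaces each curvature \code{a = 1 / c^2} by \code{a / alpha} with
#' \code{0 < alpha < 1} (the image resolution in micrometres), i.e.
#' \code{c^2 -> c^2 * alpha}. The narrower paraboloid keeps the apex and
#' tilt and strictly shrinks the interior, trimming signal at the SAM /
#' primordium boundary.
#'
#' @param p a [Paraboloid3D-class]
#' @param alpha inflation factor, strictly between 0 and 1.
#' @return the inflated [Paraboloid3D-class]
#' @export
inflateCurvature <- function(p, alpha) {
  stopifnot(is(p, "Paraboloid3D"))
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  new("Paraboloid3D", apex = p@apex, c1sq = p@c1sq * alpha,
      c2sq = p@c2sq * alpha, theta = p@theta,
      lateralComplete = p@lateralComplete)
}

# Interior membership of a paraboloid on an isotropic (z, y, x) grid:
# voxel centres whose tilt-rotated axial offset reaches the surface.
.paraboloidInterior <- function(p, dimZYX, voxelSize) {
  xs <- .axisCoords(dimZYX[3L], voxelSize)
  ys <- .axisCoords(dimZYX[2L], voxelSize)
  zs <- .axisCoords(dimZYX[1L], voxelSize)
  f <- .tiltFields(xs, zs, p@apex[c(1L, 3L)], p@theta)
  B <- f$zr - f$xr^2 / p@c1sq                     # (nz, nx)
  dy2 <- (ys - p@apex[2L])^2 / p@c2sq
  aperm(outer(B, dy2, `-`), c(1L, 3L, 2L)) >= 0
}

#' Zero a channel outside the paraboloid mask
#'
#' A voxel is interior iff its centre satisfies the paraboloid
#' inequality evaluated in the tilt-rotated frame; all other voxels of
#' the selected channel are set to 0, other channels are untouched.
#'
#' @param stack an [IsotropicStack-class]
#' @param p a [Paraboloid3D-class]
#' @param channel channel to mask
#' @return the masked stack
#' @export
applyMask <- function(stack, p, channel) {
  stopifnot(is(stack, "VoxelStack"), is(p, "Paraboloid3D"))
  if (!isIsotropic(stack)) stop("applyMask requires an isotropic stack")
  d <- dim(stack)
  zMax <- (d[1L] - 1) * stack@voxelSizeZ
  a <- getChannel(stack, channel)
  if (p@apex[3L] > zMax) {
    warning("paraboloid apex lies below the deepest slice; ",
            "channel masked to all zero")
    stack@intensities[[channel]] <- array(0, d)
    return(stack)
  }
  interior <- .paraboloidInterior(p, d, stack@voxelSizeXY)
  if (!any(interior)) stop("no interior voxel within the grid")
  a[!interior] <- 0
  stack@intensities[[channel]] <- a
  stack
}
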