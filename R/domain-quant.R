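#' @include fluor-quant.R
NULL

#' Crop a stack to the rectangle containing the SAM
#'
#' Keeps all z slices and the requested x/y window, excluding signal from
#' peripheral primordia before projecting. Bounds are 1-based voxel
#' indices, inclusive.
#'
#' @param stack a [VoxelStack-class]
#' @param rect numeric(4) \code{c(x0, x1, y0, y1)}
#' @return the cropped stack (same class, same voxel sizes)
#' @export
cropSubstack <- function(stack, rect) {
  stopifnot(is(stack, "VoxelStack"), length(rect) == 4L)
  d <- dim(stack)
  r <- as.integer(rect)
  if (r[1L] > r[2L] || r[3L] > r[4L]) stop("empty crop rectangle")
  if (r[1L] < 1L || r[2L] > d[3L] || r[3L] < 1L || r[4L] > d[2L])
    stop("crop rectangle outside the grid")
  stack@intensities <- lapply(stack@intensities, function(a)
    a[, r[3L]:r[4L], r[1L]:r[2L], drop = FALSE])
  stack
}

#' Full-axis orthogonal sum projections of one channel
#'
#' Sums the whole stack along y and along x, giving the two side views
#' (xz and yz) used for isocline analysis of expression domains.
#'
#' @param stack an [IsotropicStack-class] (or any isotropic
#'   [VoxelStack-class])
#' @param channel channel to project
#' @return list with [ProjectionImage-class] elements \code{xz} and
#'   \code{yz}
#' @export
orthogonalProjections <- function(stack, channel) {
  stopifnot(is(stack, "VoxelStack"))
  if (!isIsotropic(stack))
    stop("orthogonal projections require an isotropic stack")
  a <- getChannel(stack, channel)
  d <- dim(a)
  list(
    xz = new("ProjectionImage", pixels = apply(a, c(1L, 3L), sum),
             plane = "xz", pixelSize = stack@voxelSizeXY,
             sliceInterval = c(1, d[2L])),
    yz = new("ProjectionImage", pixels = apply(a, c(1L, 2L), sum),
             plane = "yz", pixelSize = stack@voxelSizeXY,
             sliceInterval = c(1, d[3L]))
  )
}

# Direct least-squares ellipse fit (conic form A x^2 + B xy + C y^2 +
# D x + E y + F = 0, ellipse-specific constraint 4AC - B^2 = 1).
# Data are centred before fitting for conditioning.
.fitEllipseConic <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my
  D1 <- cbind(xc^2, xc * yc, yc^2)
  D2 <- cbind(xc, yc, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  cond <- Re(4 * ev$vectors[1L, ] * ev$vectors[3L, ] - ev$vectors[2L, ]^2)
  pick <- which(cond > 0)
  if (!length(pick)) return(NULL)
  a1 <- Re(ev$vectors[, pick[1L]])
  conic <- c(a1, as.numeric(Tm %*% a1))
  names(conic) <- c("A", "B", "C", "D", "E", "F")
  # un-centre: substitute x -> x - mx, y -> y - my
  A <- conic["A"]; B <- conic["B"]; C <- conic["C"]
  D <- conic["D"] - 2 * A * mx - B * my
  E <- conic["E"] - 2 * C * my - B * mx
  F <- conic["F"] + A * mx^2 + B * mx * my + C * my^2 -
    conic["D"] * mx - conic["E"] * my
  c(A = unname(A), B = unname(B), C = unname(C),
    D = unname(D), E = unname(E), F = unname(F))
}

# Conic coefficients -> centre, semi-axes and axis directions.
.conicGeometry <- function(cf) {
  M <- matrix(c(cf["A"], cf["B"] / 2, cf["B"] / 2, cf["C"]), 2L, 2L)
  ctr <- tryCatch(solve(2 * M, -c(cf["D"], cf["E"])),
                  error = function(e) NULL)
  if (is.null(ctr)) return(NULL)
  const <- as.numeric(cf["A"] * ctr[1L]^2 + cf["B"] * prod(ctr) +
    cf["C"] * ctr[2L]^2 + cf["D"] * ctr[1L] + cf["E"] * ctr[2L] +
    cf["F"])
  ev <- eigen(M, symmetric = TRUE)
  ax2 <- -const / ev$values
  if (any(ax2 <= 0)) return(NULL)
  list(center = as.numeric(ctr), semi = sqrt(ax2), dirs = ev$vectors)
}

# Second-moment (equivalent) ellipse of contour points: exact for
# uniformly sampled circles, fallback when too few points for the conic.
.momentEllipse <- function(x, y) {
  ctr <- c(mean(x), mean(y))
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE)
  list(center = ctr, semi = sqrt(pmax(2 * ev$values, 0)),
       dirs = ev$vectors)
}

#' Fit an ellipse to a fractional-maximum isocline of a projection
#'
#' The projection is lightly smoothed (Gaussian, \code{smoothSigmaPx}
#' pixels) so the maximum is not noise-dominated, then the level-set
#' contour at \code{fraction} of the maximum is extracted with sub-pixel
#' linear interpolation (marching squares). The contour enclosing the
#' maximum is fitted with a direct least-squares conic (second-moment
#' fallback below 6 points). The fitted axis closer to the image vertical
#' (depth direction) is reported as the domain height, the other as the
#' width; both are full axis lengths in micrometres.
#'
#' A contour touching the image border, or an empty threshold region, is
#' an error rather than a silent fit.
#'
#' @param projection a [ProjectionImage-class] with positive maximum
#' @param fraction threshold fraction of the maximum (default 0.5)
#' @param smoothSigmaPx pre-threshold smoothing sd in pixels (0 disables)
#' @return a [DomainEllipse-class]
#' @export
isoclineEllipse <- function(projection, fraction = 0.5,
                            smoothSigmaPx = 1) {
  stopifnot(is(projection, "ProjectionImage"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  img <- projection@pixels
  if (smoothSigmaPx > 0) img <- .gaussSmooth(img, smoothSigmaPx)
  mx <- max(img)
  if (mx <= 0) stop("projection has no positive signal")
  px <- projection@pixelSize
  depth <- .axisCoords(nrow(img), px)
  lateral <- .axisCoords(ncol(img), px)
  cl <- grDevices::contourLines(depth, lateral, img,
                                levels = fraction * mx)
  if (!length(cl)) stop("threshold region empty (no isocline found)")
  # pick the contour enclosing the image maximum; fall back to largest
  imax <- which(img == mx, arr.ind = TRUE)[1L, ]
  pmaxc <- c(depth[imax[1L]], lateral[imax[2L]])
  encloses <- vapply(cl, function(cc)
    .pointInPolygon(pmaxc[1L], pmaxc[2L], cc$x, cc$y), TRUE)
  areas <- vapply(cl, function(cc) abs(.polyArea(cc$x, cc$y)), 0)
  k <- if (any(encloses)) which(encloses)[which.max(areas[encloses])]
       else which.max(areas)
  cc <- cl[[k]]
  eps <- px / 2
  if (min(cc$x) < min(depth) + eps || max(cc$x) > max(depth) - eps ||
      min(cc$y) < min(lateral) + eps || max(cc$y) > max(lateral) - eps)
    stop("isocline touches the image border; domain not fully contained")
  # fit in (lateral, depth) coordinates; vertical = depth
  lx <- cc$y; dy <- cc$x
  n <- length(lx)
  geom <- NULL
  method <- "conic"
  if (n >= 6L) {
    cf <- .fitEllipseConic(lx, dy)
    if (!is.null(cf)) geom <- .conicGeometry(cf)
  }
  if (is.null(geom)) {
    geom <- .momentEllipse(lx, dy)
    method <- "moments"
  }
  # axis whose direction is closer to the vertical (depth) axis = height
  vert <- abs(geom$dirs[2L, ])
  hIdx <- which.max(vert)
  wIdx <- if (hIdx == 1L) 2L else 1L
  ang <- acos(pmin(1, vert[hIdx])) * 180 / pi
  new("DomainEllipse",
      center = geom$center, heightUm = 2 * geom$semi[hIdx],
      widthUm = 2 * geom$semi[wIdx], orientationDeg = ang,
      fraction = fraction, plane = projection@plane,
      nContour = as.integer(n), method = method)
}

# Ray-casting point-in-polygon (polygon closed implicitly).
.pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

# Signed shoelace area.
.polyArea <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Combine the two side-view ellipses into one domain height and width
#'
#' The two orthogonal views are treated symmetrically: the reported
#' height and width are the means of the per-view full axis lengths, and
#' both per-view values are retained.
#'
#' @param eXZ,eYZ [DomainEllipse-class] objects from the xz and yz views
#' @return list with \code{height_um}, \code{width_um} and a
#'   \code{per_view} data.frame
#' @export
domainDimensions <- function(eXZ, eYZ) {
  stopifnot(is(eXZ, "DomainEllipse"), is(eYZ, "DomainEllipse"))
  list(
    height_um = mean(c(eXZ@heightUm, eYZ@heightUm)),
    width_um = mean(c(eXZ@widthUm, eYZ@widthUm)),
    per_view = data.frame(
      plane = c(eXZ@plane, eYZ@plane),
      height_um = c(eXZ@heightUm, eYZ@heightUm),
      width_um = c(eXZ@widthUm, eYZ@widthUm))
  )
}

#' Peripheral-zone metrics from meristem and OC widths
#'
#' The peripheral-zone (PZ) width is half the difference between the
#' meristem width and the width of the WUS-marked organising-centre (OC)
#' domain: \code{(W - w_oc) / 2}; the PZ/OC ratio divides this by the OC
#' width. Vectorised over paired inputs.
#'
#' @param meristemWidthUm meristem width W, micrometres (from the
#'   morphometric measurement, not re-derived here)
#' @param ocWidthUm WUS-domain (OC) width, micrometres; must satisfy
#'   \code{0 <= w_oc <= W}, and be positive for the ratio
#' @return data.frame with columns \code{meristem_width_um},
#'   \code{oc_width_um}, \code{periphery_um}, \code{pz_oc_ratio}
#' @export
peripheryMetrics <- function(meristemWidthUm, ocWidthUm) {
  if (length(meristemWidthUm) != length(ocWidthUm))
    stop("inputs must be paired")
  if (any(ocWidthUm < 0) || any(meristemWidthUm < ocWidthUm))
    stop("widths must satisfy 0 <= oc width <= meristem width")
  if (any(ocWidthUm == 0))
    stop("oc width of 0 leaves the PZ/OC ratio undefined")
  periph <- (meristemWidthUm - ocWidthUm) / 2
  data.frame(
    meristem_width_um = meristemWidthUm,
    oc_width_um = ocWidthUm,
    periphery_um = periph,
    pz_oc_ratio = periph / ocWidthUm
  )
}
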