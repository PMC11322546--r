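#' @import methods
NULL

#' VoxelStack: a multi-channel confocal z-stack
#'
#' Container for one acquisition: per-channel 3D intensity grids indexed
#' \code{(z, y, x)} together with the physical voxel sizes in micrometres.
#' Slice \code{z = 1} is the top (apex-side) slice and \code{z} increases
#' into the tissue. Coordinates are voxel-centred: the physical position of
#' 1-based index \code{i} along an axis of spacing \code{s} is
#' \code{(i - 1) * s} micrometres.
#'
#' @slot intensities named list of 3D numeric arrays, one per channel, all
#'   sharing one \code{(z, y, x)} shape; all values must be non-negative.
#' @slot voxelSizeXY lateral pixel size, micrometres per pixel.
#' @slot voxelSizeZ axial step size, micrometres per slice (confocal
#'   acquisitions here typically use 0.4).
#'
#' @seealso [VoxelStack()], [resampleIsotropic()], [readStack()]
#' @exportClass VoxelStack
setClass("VoxelStack",
  representation(
    intensities = "list",
    voxelSizeXY = "numeric",
    voxelSizeZ  = "numeric"
  )
)

setValidity("VoxelStack", function(object) {
  msg <- character()
  ints <- object@intensities
  if (length(ints) < 1L) msg <- c(msg, "at least one channel is required")
  if (is.null(names(ints)) || any(!nzchar(names(ints))) ||
      anyDuplicated(names(ints)))
    msg <- c(msg, "channels must have unique non-empty names")
  dims <- lapply(ints, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msg <- c(msg, "each channel must be a 3D (z, y, x) array")
  if (length(dims) > 1L &&
      !all(vapply(dims[-1L], identical, TRUE, y = dims[[1L]])))
    msg <- c(msg, "all channels must share one grid shape")
  if (any(vapply(ints, function(a) anyNA(a) || min(a) < 0, TRUE)))
    msg <- c(msg, "intensities must be non-negative and non-missing")
  for (s in c("voxelSizeXY", "voxelSizeZ")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (length(msg)) msg else TRUE
})

#' IsotropicStack: a stack resampled to one voxel size on all axes
#'
#' Produced by [resampleIsotropic()]. The common voxel size equals the
#' source lateral pixel size; the slice count is never smaller than the
#' source slice count.
#'
#' @slot provenance free-text note recording the source stack and the
#'   interpolation used.
#' @exportClass IsotropicStack
setClass("IsotropicStack",
  contains = "VoxelStack",
  representation(provenance = "character")
)

setValidity("IsotropicStack", function(object) {
  if (!isTRUE(all.equal(object@voxelSizeXY, object@voxelSizeZ)))
    return("voxel size must be identical on all axes")
  TRUE
})

#' Parabola2D: a tilted parabola fitted to a SAM outline in a projection
#'
#' In a frame rotated by \code{theta} degrees relative to the image
#' vertical the curve is \code{w = w0 + a * (u - u0)^2}, with \code{u} the
#' lateral coordinate and \code{w} the depth coordinate (increasing into
#' the tissue, so the apex is the minimum). The apex is reported in the
#' unrotated frame.
#'
#' @slot apex numeric(2), \code{(u0, w0)} in micrometres, unrotated frame.
#' @slot curvature the coefficient \code{a} in 1/micrometres; positive.
#' @slot theta orientation of the fitting frame, degrees.
#' @slot rss residual sum of squares of the selected fit.
#' @slot gof R-squared-style goodness of fit (1 - RSS/TSS).
#' @exportClass Parabola2D
setClass("Parabola2D",
  representation(
    apex = "numeric", curvature = "numeric", theta = "numeric",
    rss = "numeric", gof = "numeric"
  )
)

setValidity("Parabola2D", function(object) {
  if (length(object@apex) != 2L) return("apex must be numeric(2)")
  if (object@curvature <= 0) return("curvature must be positive")
  TRUE
})

#' Paraboloid3D: the 3D mask geometry
#'
#' An elliptic paraboloid used to mask the meristem interior. In a frame
#' rotated by \code{theta} degrees about the y axis through the apex, the
#' surface is \code{z = (x)^2 / c1sq + (y)^2 / c2sq} with apex-relative
#' coordinates; voxels at or below the surface (larger rotated z) are
#' interior. When only the xz parabola could be fitted
#' (\code{lateralComplete = FALSE}), the lateral denominator copies the
#' xz one (\code{c2sq = c1sq}).
#'
#' @slot apex numeric(3), \code{(x0, y0, z0)} micrometres.
#' @slot c1sq,c2sq denominators of the quadratic terms, square
#'   micrometres; the reciprocal of each is the parabola curvature.
#' @slot theta tilt about the y axis, degrees.
#' @slot lateralComplete whether the yz view contributed its own curvature.
#' @exportClass Paraboloid3D
setClass("Paraboloid3D",
  representation(
    apex = "numeric", c1sq = "numeric", c2sq = "numeric",
    theta = "numeric", lateralComplete = "logical"
  )
)

setValidity("Paraboloid3D", function(object) {
  if (length(object@apex) != 3L) return("apex must be numeric(3)")
  if (object@c1sq <= 0 || object@c2sq <= 0)
    return("c1sq and c2sq must be positive")
  if (!object@lateralComplete && !isTRUE(all.equal(object@c2sq, object@c1sq)))
    return("when lateralComplete is FALSE, c2sq must equal c1sq")
  TRUE
})

#' ProjectionImage: a 2D sum projection of one channel
#'
#' Rows index depth (z, micrometres downward from the top slice) and
#' columns index the retained lateral axis (x for plane "xz", y for
#' plane "yz").
#'
#' @slot pixels non-negative matrix (depth rows, lateral columns).
#' @slot plane "xz" or "yz".
#' @slot pixelSize micrometres per pixel (isotropic).
#' @slot sliceInterval 1-based slice range that was collapsed, or the
#'   full range for whole-axis projections.
#' @exportClass ProjectionImage
setClass("ProjectionImage",
  representation(
    pixels = "matrix", plane = "character", pixelSize = "numeric",
    sliceInterval = "numeric"
  )
)

setValidity("ProjectionImage", function(object) {
  if (!object@plane %in% c("xz", "yz")) return("plane must be 'xz' or 'yz'")
  if (object@pixelSize <= 0) return("pixel size must be positive")
  if (min(object@pixels) < 0) return("projection must be non-negative")
  TRUE
})

#' MaskRegion: the depth-limited interior of a paraboloid on a voxel grid
#'
#' Voxel membership for the upper region of a [Paraboloid3D-class]: interior
#' voxels whose distance from the apex, measured along the (possibly
#' tilted) paraboloid axis, does not exceed \code{depthUm}.
#'
#' @slot mask logical 3D array on the (z, y, x) grid.
#' @slot depthUm depth limit in micrometres (20 or 50 in routine use).
#' @slot voxelSize isotropic voxel size of the grid, micrometres.
#' @slot paraboloid the source geometry.
#' @exportClass MaskRegion
setClass("MaskRegion",
  representation(
    mask = "array", depthUm = "numeric", voxelSize = "numeric",
    paraboloid = "Paraboloid3D"
  )
)

setValidity("MaskRegion", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    return("mask must be a logical 3D array")
  if (object@depthUm <= 0) return("depth must be positive")
  if (object@voxelSize <= 0) return("voxel size must be positive")
  TRUE
})

#' FluorMeasure: the fluorescence-concentration proxy for one region
#'
#' Total reporter intensity, region volume, and their ratio. For display
#' alongside published values the concentration is additionally divided
#' by 1000 (\code{reportedConcentration}).
#'
#' @slot totalIntensity sum of voxel intensities in the region (a.u.).
#' @slot volumeUm3 summed voxel volume, cubic micrometres.
#' @slot concentration \code{totalIntensity / volumeUm3}.
#' @slot reportedConcentration \code{concentration / 1000}.
#' @slot sigma Gaussian smoothing sigma in pixels that was applied inside
#'   the mask before measuring, or \code{NA} when none was.
#' @slot depthUm depth limit of the measured region.
#' @slot channel channel name measured.
#' @exportClass FluorMeasure
setClass("FluorMeasure",
  representation(
    totalIntensity = "numeric", volumeUm3 = "numeric",
    concentration = "numeric", reportedConcentration = "numeric",
    sigma = "numeric", depthUm = "numeric", channel = "character"
  )
)

setValidity("FluorMeasure", function(object) {
  if (object@volumeUm3 <= 0) return("volume must be positive")
  if (!isTRUE(all.equal(object@concentration * object@volumeUm3,
                        object@totalIntensity, tolerance = 1e-8)))
    return("concentration * volume must equal total intensity")
  TRUE
})

#' DomainEllipse: half-maximum isocline ellipse of an expression domain
#'
#' Ellipse fitted to the level-set contour of a sum projection at
#' \code{fraction} of its maximum. \code{heightUm} is the full length of
#' the axis closer to the image vertical (depth direction); \code{widthUm}
#' the full length of the other axis.
#'
#' @slot center numeric(2), (lateral, depth) micrometres.
#' @slot heightUm,widthUm full axis lengths, micrometres.
#' @slot orientationDeg angle between the height axis and the image
#'   vertical, degrees.
#' @slot fraction threshold fraction of the projection maximum (0.5
#'   default in routine use).
#' @slot plane projection plane the ellipse came from.
#' @slot nContour number of contour points used.
#' @slot method "conic" (direct least-squares fit) or "moments" (fallback).
#' @exportClass DomainEllipse
setClass("DomainEllipse",
  representation(
    center = "numeric", heightUm = "numeric", widthUm = "numeric",
    orientationDeg = "numeric", fraction = "numeric", plane = "character",
    nContour = "integer", method = "character"
  )
)

setValidity("DomainEllipse", function(object) {
  if (object@heightUm <= 0 || object@widthUm <= 0)
    return("axes must be positive")
  if (object@fraction <= 0 || object@fraction >= 1)
    return("fraction must lie strictly between 0 and 1")
  TRUE
})

#' DomeSpec: geometry of a synthetic meristem dome
#'
#' The untilted surface is \code{z = z0 + a1 (x - x0)^2 + a2 (y - y0)^2}
#' (z increasing into the tissue, so the apex is the shallowest surface
#' point); the whole surface is then rigidly rotated by \code{tiltDeg}
#' about the y axis through the apex. Channel 0 of a generated stack is a
#' Gaussian cell-wall shell around this surface.
#'
#' @slot apexUm numeric(3), apex position (x0, y0, z0), micrometres.
#' @slot curvatures numeric(2), (a1, a2) in 1/micrometres, both positive.
#' @slot tiltDeg rotation about the y axis, degrees; |tilt| < 45.
#' @slot wallThicknessUm Gaussian sd of the wall shell, micrometres.
#' @slot wallAmplitude peak wall intensity (a.u.).
#' @slot primordia list of optional lateral bumps, each a list with
#'   elements \code{offsetUm} (numeric(2), lateral offset from the apex),
#'   \code{amplitudeUm} (bump height) and \code{sigmaUm} (bump extent).
#' @exportClass DomeSpec
setClass("DomeSpec",
  representation(
    apexUm = "numeric", curvatures = "numeric", tiltDeg = "numeric",
    wallThicknessUm = "numeric", wallAmplitude = "numeric",
    primordia = "list"
  )
)

setValidity("DomeSpec", function(object) {
  if (length(object@apexUm) != 3L) return("apexUm must be numeric(3)")
  if (length(object@curvatures) != 2L || any(object@curvatures <= 0))
    return("curvatures must be two positive numbers")
  if (abs(object@tiltDeg) >= 45) return("|tilt| must be < 45 degrees")
  if (object@wallThicknessUm <= 0) return("wall thickness must be positive")
  TRUE
})

#' ReporterSpec: a synthetic fluorescence reporter channel
#'
#' Three modes emulate the reporter types analysed in the quantification
#' pipelines: \code{"uniform-interior"} (diffuse translational fusions
#' such as SOC1:GFP / AP2:VENUS: constant value \code{value} everywhere
#' below the dome surface), \code{"graded"} (value decaying linearly with
#' depth below the surface) and \code{"nuclear-gaussian"} (a 3D Gaussian
#' blob emulating a nuclear-localised transcriptional reporter domain such
#' as WUS::3xVENUS-NLS or CLV3::mCHERRY-NLS). A constant
#' \code{background} is added everywhere; optional Poisson shot noise
#' (gain \code{poissonGain} > 0) and Gaussian read noise (\code{readSd})
#' follow, after which values are clipped at 0.
#'
#' @slot name channel name.
#' @slot mode one of "uniform-interior", "graded", "nuclear-gaussian".
#' @slot value interior value (uniform / graded modes), a.u. per voxel.
#' @slot gradeLengthUm depth (micrometres) over which a graded reporter
#'   decays linearly from \code{value} to 0.
#' @slot centerUm numeric(3) Gaussian centre (nuclear-gaussian mode).
#' @slot sigmaUm numeric(3) Gaussian sds (x, y, z), micrometres.
#' @slot amplitude Gaussian peak value, a.u.
#' @slot background constant offset, a.u.
#' @slot poissonGain photons-per-count gain for shot noise; 0 disables.
#' @slot readSd Gaussian read-noise sd, a.u.; 0 disables.
#' @exportClass ReporterSpec
setClass("ReporterSpec",
  representation(
    name = "character", mode = "character", value = "numeric",
    gradeLengthUm = "numeric", centerUm = "numeric", sigmaUm = "numeric",
    amplitude = "numeric", background = "numeric",
    poissonGain = "numeric", readSd = "numeric"
  )
)

setValidity("ReporterSpec", function(object) {
  if (!object@mode %in% c("uniform-interior", "graded", "nuclear-gaussian"))
    return("unknown reporter mode")
  if (object@amplitude < 0 || object@value < 0 || object@background < 0)
    return("amplitudes must be non-negative")
  if (object@mode == "nuclear-gaussian" &&
      (length(object@sigmaUm) != 3L || any(object@sigmaUm <= 0)))
    return("sigmaUm must be three positive numbers")
  if (object@poissonGain < 0 || object@readSd < 0)
    return("noise parameters must be non-negative")
  TRUE
})
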