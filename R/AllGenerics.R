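#' @include AllClasses.R
NULL

#' Channel names of a stack
#' @param x a [VoxelStack-class]
#' @return character vector of channel names
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "VoxelStack", function(x) names(x@intensities))

#' Extract one channel's intensity array
#' @param x a [VoxelStack-class]
#' @param channel channel name or 1-based index
#' @return the 3D (z, y, x) intensity array
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname getChannel
#' @export
setMethod("getChannel", "VoxelStack", function(x, channel) {
  if (is.character(channel) && !channel %in% names(x@intensities))
    stop("unknown channel: ", channel)
  x@intensities[[channel]]
})

#' Voxel sizes of a stack in micrometres
#' @param x a [VoxelStack-class]
#' @return named numeric: \code{xy} and \code{z} spacing
#' @export
setGeneric("voxelSizes", function(x) standardGeneric("voxelSizes"))

#' @rdname voxelSizes
#' @export
setMethod("voxelSizes", "VoxelStack",
  function(x) c(xy = x@voxelSizeXY, z = x@voxelSizeZ))

#' Grid dimensions (z, y, x) of a stack
#' @param x a [VoxelStack-class]
#' @export
setMethod("dim", "VoxelStack", function(x) dim(x@intensities[[1L]]))

#' Is the stack isotropic?
#' @param x a [VoxelStack-class]
#' @return TRUE when the z spacing equals the lateral pixel size
#' @export
isIsotropic <- function(x) {
  stopifnot(is(x, "VoxelStack"))
  isTRUE(all.equal(x@voxelSizeXY, x@voxelSizeZ))
}

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object)
  cat(sprintf("%s: %d channel(s) [%s], grid %d x %d x %d (z,y,x)\n",
              class(object), length(object@intensities),
              paste(channelNames(object), collapse = ", "),
              d[1L], d[2L], d[3L]))
  cat(sprintf("  voxel size: %.3g (xy) x %.3g (z) um\n",
              object@voxelSizeXY, object@voxelSizeZ))
  if (is(object, "IsotropicStack") && length(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "Parabola2D", function(object) {
  cat(sprintf(
    "Parabola2D: apex (%.3f, %.3f) um, a = %.5g 1/um, theta = %.2f deg\n",
    object@apex[1L], object@apex[2L], object@curvature, object@theta))
  cat(sprintf("  RSS = %.4g, goodness of fit = %.4f\n",
              object@rss, object@gof))
})

setMethod("show", "Paraboloid3D", function(object) {
  cat(sprintf(
    "Paraboloid3D: apex (%.2f, %.2f, %.2f) um, c1^2 = %.4g, c2^2 = %.4g um^2\n",
    object@apex[1L], object@apex[2L], object@apex[3L],
    object@c1sq, object@c2sq))
  cat(sprintf("  tilt = %.2f deg; lateral view %s\n", object@theta,
              if (object@lateralComplete) "complete" else
                "incomplete (c2^2 = c1^2)"))
})

setMethod("show", "FluorMeasure", function(object) {
  cat(sprintf(
    "FluorMeasure [%s, depth %g um]: total %.4g a.u. / %.4g um^3\n",
    object@channel, object@depthUm, object@totalIntensity,
    object@volumeUm3))
  cat(sprintf("  concentration %.5g a.u./um^3 (reported %.5g)%s\n",
              object@concentration, object@reportedConcentration,
              if (is.na(object@sigma)) "" else
                sprintf(", smoothed sigma = %g px", object@sigma)))
})

setMethod("show", "DomainEllipse", function(object) {
  cat(sprintf(
    "DomainEllipse [%s, f = %g]: height %.2f um, width %.2f um (%s fit)\n",
    object@plane, object@fraction, object@heightUm, object@widthUm,
    object@method))
})

#' Accessors for measurement objects
#'
#' Small single-slot readers so downstream code never touches slots
#' directly.
#' @param x a measurement object
#' @name measure-accessors
NULL

#' @rdname measure-accessors
#' @export
totalIntensity <- function(x) x@totalIntensity

#' @rdname measure-accessors
#' @export
regionVolume <- function(x) x@volumeUm3

#' @rdname measure-accessors
#' @export
reportedConcentration <- function(x) x@reportedConcentration

#' @rdname measure-accessors
#' @export
domainHeight <- function(x) x@heightUm

#' @rdname measure-accessors
#' @export
domainWidth <- function(x) x@widthUm

#' @rdname measure-accessors
#' @export
apexPosition <- function(x) x@apex

#' @rdname measure-accessors
#' @export
curvature <- function(x) {
  if (is(x, "Parabola2D")) return(x@curvature)
  if (is(x, "Paraboloid3D")) return(c(a1 = 1 / x@c1sq, a2 = 1 / x@c2sq))
  stop("no curvature accessor for class ", class(x))
}
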