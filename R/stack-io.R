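#' @include utils.R
NULL

#' Construct a VoxelStack
#'
#' @param intensities a 3D \code{(z, y, x)} array for a single channel, or
#'   a named list of such arrays (one per channel).
#' @param voxelSizeXY lateral pixel size, micrometres.
#' @param voxelSizeZ axial step, micrometres.
#' @return a [VoxelStack-class]
#' @examples
#' a <- array(0, c(8, 16, 16))
#' VoxelStack(list(wall = a), voxelSizeXY = 0.2, voxelSizeZ = 0.4)
#' @export
VoxelStack <- function(intensities, voxelSizeXY, voxelSizeZ) {
  if (is.array(intensities)) intensities <- list(ch1 = intensities)
  if (is.null(names(intensities)))
    names(intensities) <- paste0("ch", seq_along(intensities))
  new("VoxelStack", intensities = intensities,
      voxelSizeXY = voxelSizeXY, voxelSizeZ = voxelSizeZ)
}

# Sidecar path used for voxel-size metadata (baseline TIFF writers differ
# in their resolution-tag dialects, so the package writes its own).
.sidecarPath <- function(path) paste0(path, ".json")

#' Write a stack to TIFF with voxel-size metadata
#'
#' Pages are written channel-fastest (ImageJ hyperstack page order).
#' Integer-valued stacks fitting 16 bits are stored losslessly as uint16;
#' anything else is stored as 32-bit float scaled into [0, 1], with the
#' scale recorded in the metadata. Voxel sizes, channel names, grid shape
#' and storage details go to a JSON sidecar \code{<path>.json}.
#'
#' @param stack a [VoxelStack-class]
#' @param path output TIFF path
#' @return \code{path}, invisibly
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "VoxelStack"))
  d <- dim(stack)
  chn <- channelNames(stack)
  allv <- unlist(lapply(stack@intensities, range))
  isInt <- all(vapply(stack@intensities,
                      function(a) all(a == round(a)), TRUE)) &&
    max(allv) <= 65535
  if (isInt) {
    dtype <- "uint16"; scale <- 65535
  } else {
    dtype <- "float32"; scale <- max(allv, 1)
  }
  pages <- vector("list", d[1L] * length(chn))
  k <- 0L
  for (z in seq_len(d[1L])) {
    for (ch in chn) {
      k <- k + 1L
      pages[[k]] <- stack@intensities[[ch]][z, , ] / scale
    }
  }
  tiff::writeTIFF(pages, path, compression = "none",
                  bits.per.sample = if (isInt) 16L else 32L)
  meta <- list(
    format = "apexquant-stack",
    voxel_size_xy_um = stack@voxelSizeXY,
    voxel_size_z_um = stack@voxelSizeZ,
    channels = as.list(chn),
    dim_zyx = as.integer(d),
    dtype = dtype,
    scale = scale
  )
  jsonlite::write_json(meta, .sidecarPath(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel z-stack from TIFF
#'
#' Voxel sizes are taken from, in order of precedence: the
#' \code{voxelSizes} override; the JSON sidecar written by
#' [writeStack()]; an ImageJ-style description tag (\code{spacing=} for z,
#' \code{channels=} for the channel count) combined with TIFF resolution
#' tags for the lateral size. A file carrying none of these is an error.
#'
#' @param path TIFF file readable as (channels x) z x y x pages
#' @param voxelSizes optional numeric(2) \code{c(xy, z)} override, um.
#' @param nChannels optional channel count when the file carries no
#'   channel metadata (defaults to 1).
#' @return a [VoxelStack-class]
#' @export
readStack <- function(path, voxelSizes = NULL, nChannels = NULL) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  side <- .sidecarPath(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  isFloat <- !is.null(meta) && identical(meta$dtype, "float32")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = !isFloat)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1L]])

  vsXY <- vsZ <- NA_real_
  chn <- NULL
  scale <- if (isFloat) meta$scale else 1
  if (!is.null(meta)) {
    vsXY <- meta$voxel_size_xy_um
    vsZ <- meta$voxel_size_z_um
    chn <- unlist(meta$channels)
  } else {
    desc <- info$description
    if (!is.null(desc)) {
      sp <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1L]]
      if (length(sp) == 2L) vsZ <- as.numeric(sp[2L])
      nc <- regmatches(desc, regexec("channels=([0-9]+)", desc))[[1L]]
      if (length(nc) == 2L && is.null(nChannels))
        nChannels <- as.integer(nc[2L])
    }
    if (!is.null(info$x.resolution) && info$x.resolution > 0)
      vsXY <- 1 / info$x.resolution
  }
  if (!is.null(voxelSizes)) {
    stopifnot(length(voxelSizes) == 2L, all(voxelSizes > 0))
    vsXY <- voxelSizes[[1L]]; vsZ <- voxelSizes[[2L]]
  }
  if (!is.finite(vsXY) || !is.finite(vsZ))
    stop("voxel sizes unknown: no sidecar/metadata and no override given")

  nC <- if (!is.null(chn)) length(chn) else
    if (!is.null(nChannels)) as.integer(nChannels) else 1L
  if (length(pages) %% nC != 0L)
    stop("page count ", length(pages), " is not a multiple of the ",
         "channel count ", nC)
  nZ <- length(pages) %/% nC
  if (is.null(chn)) chn <- paste0("ch", seq_len(nC))
  pd <- dim(pages[[1L]])
  ints <- stats::setNames(vector("list", nC), chn)
  for (ci in seq_len(nC)) {
    a <- array(0, c(nZ, pd[1L], pd[2L]))
    for (z in seq_len(nZ)) a[z, , ] <- pages[[(z - 1L) * nC + ci]] * scale
    if (min(a) < 0) stop("negative intensities after decoding")
    ints[[ci]] <- a
  }
  VoxelStack(ints, voxelSizeXY = vsXY, voxelSizeZ = vsZ)
}

# Catmull-Rom (Keys a = -0.5) weights at fractional position t in [0, 1)
.crWeights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  c(0.5 * (-t3 + 2 * t2 - t),
    0.5 * (3 * t3 - 5 * t2 + 2),
    0.5 * (-3 * t3 + 4 * t2 + t),
    0.5 * (t3 - t2))
}

#' Resample a stack to isotropic voxels
#'
#' Increases the number of slices so that the axial spacing equals the
#' lateral pixel size, interpolating each \code{(y, x)} column along z
#' with an edge-clamped Catmull-Rom cubic kernel (the bicubic kernel in
#' its 1-D separable form; the xy planes are untouched). Interpolation
#' overshoot below zero is clipped to 0. An already isotropic stack is
#' returned unchanged (up to class).
#'
#' @param stack a [VoxelStack-class] with \code{voxelSizeZ >=
#'   voxelSizeXY}; finer axial than lateral sampling is refused since it
#'   signals inverted anisotropy metadata.
#' @return an [IsotropicStack-class]
#' @export
resampleIsotropic <- function(stack) {
  stopifnot(is(stack, "VoxelStack"))
  dxy <- stack@voxelSizeXY; dz <- stack@voxelSizeZ
  if (dz < dxy && !isTRUE(all.equal(dz, dxy)))
    stop("voxel_size_z < voxel_size_xy: refusing to downsample along z")
  if (isTRUE(all.equal(dz, dxy))) {
    return(new("IsotropicStack", intensities = stack@intensities,
               voxelSizeXY = dxy, voxelSizeZ = dxy,
               provenance = "already isotropic; no interpolation"))
  }
  d <- dim(stack)
  nz <- d[1L]
  nzNew <- floor((nz - 1) * dz / dxy) + 1L
  sPos <- (seq_len(nzNew) - 1) * dxy / dz     # 0-based source index space
  i0 <- pmin(floor(sPos), nz - 1)
  tFrac <- sPos - i0
  clampIdx <- function(i) pmin(pmax(i, 0), nz - 1) + 1L
  ints <- lapply(stack@intensities, function(a) {
    out <- array(0, c(nzNew, d[2L], d[3L]))
    for (k in seq_len(nzNew)) {
      w <- .crWeights(tFrac[k])
      idx <- clampIdx(i0[k] + (-1:2))
      sl <- w[1L] * a[idx[1L], , ] + w[2L] * a[idx[2L], , ] +
        w[3L] * a[idx[3L], , ] + w[4L] * a[idx[4L], , ]
      out[k, , ] <- pmax(sl, 0)
    }
    out
  })
  new("IsotropicStack", intensities = ints,
      voxelSizeXY = dxy, voxelSizeZ = dxy,
      provenance = sprintf(
        "resampled z %g -> %g um (Catmull-Rom cubic, edge-clamped)",
        dz, dxy))
}

#' Write a measurement table to CSV
#'
#' Three schemas are understood. \code{"morph"}: one row per meristem with
#' columns \code{genotype, timepoint_d, height_um, width_um, area_um2,
#' primordium_identity, experiment_id} (validated). \code{"fluor"}: a list
#' of [FluorMeasure-class] objects (plus optional \code{ids}) flattened to
#' columns including \code{reported_concentration}. \code{"generic"}: any
#' data.frame, written as-is.
#'
#' @param records the table (see Details) or list of measures
#' @param path output CSV path
#' @param what one of "morph", "fluor", "generic"
#' @param ids optional identifier column for \code{what = "fluor"}
#' @return the data.frame written, invisibly
#' @export
writeTable <- function(records, path, what = c("generic", "morph", "fluor"),
                       ids = NULL) {
  what <- match.arg(what)
  df <- switch(what,
    morph = .checkMorphRecords(records),
    fluor = {
      stopifnot(all(vapply(records, is, TRUE, class2 = "FluorMeasure")))
      data.frame(
        id = if (is.null(ids)) seq_along(records) else ids,
        channel = vapply(records, function(m) m@channel, ""),
        depth_um = vapply(records, function(m) m@depthUm, 0),
        total_intensity = vapply(records, totalIntensity, 0),
        volume_um3 = vapply(records, regionVolume, 0),
        concentration = vapply(records, function(m) m@concentration, 0),
        reported_concentration = vapply(records, reportedConcentration, 0),
        smoothing_sigma_px = vapply(records, function(m) m@sigma, 0)
      )
    },
    generic = as.data.frame(records)
  )
  .writeCsv(df, path)
  invisible(df)
}

#' Read a measurement table written by [writeTable()]
#' @param path CSV path
#' @param what validate as "morph" or accept "generic"
#' @return data.frame
#' @export
readTable <- function(path, what = c("generic", "morph")) {
  what <- match.arg(what)
  df <- .readCsv(path)
  if (what == "morph") .checkMorphRecords(df)
  df
}
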