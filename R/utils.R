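#' @include AllGenerics.R
NULL

# 2x2 rotation matrix for an angle in degrees (counter-clockwise)
.rot2 <- function(thetaDeg) {
  th <- thetaDeg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

# Normalised sampled Gaussian kernel, radius 3 sigma (at least 1 px).
.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Convolve a 2D or 3D array with a 1D kernel along one axis, zero-padded.
.convAxis <- function(a, kern, axis) {
  nd <- length(dim(a))
  n <- dim(a)[axis]
  r <- (length(kern) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (j in seq_along(kern)) {
    off <- j - 1L - r
    dst <- seq_len(n)
    src <- dst + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    d <- dst[keep]; s <- src[keep]
    if (nd == 2L) {
      if (axis == 1L) out[d, ] <- out[d, , drop = FALSE] +
          kern[j] * a[s, , drop = FALSE]
      else out[, d] <- out[, d, drop = FALSE] +
          kern[j] * a[, s, drop = FALSE]
    } else {
      if (axis == 1L) out[d, , ] <- out[d, , , drop = FALSE] +
          kern[j] * a[s, , , drop = FALSE]
      else if (axis == 2L) out[, d, ] <- out[, d, , drop = FALSE] +
          kern[j] * a[, s, , drop = FALSE]
      else out[, , d] <- out[, , d, drop = FALSE] +
          kern[j] * a[, , s, drop = FALSE]
    }
  }
  out
}

# Separable Gaussian smoothing of a 2D or 3D array (isotropic sigma, px).
.gaussSmooth <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- .gaussKernel(sigma)
  for (ax in seq_along(dim(a))) a <- .convAxis(a, k, ax)
  a
}

# Mask-weighted (renormalised) Gaussian smoothing: inside the mask the
# result is conv(a * m) / conv(m), so edge voxels are not diluted by the
# zeroed exterior; outside the mask values are returned untouched.
.gaussSmoothMasked <- function(a, mask, sigma) {
  if (sigma <= 0) return(a)
  m <- array(as.numeric(mask), dim(a))
  num <- .gaussSmooth(a * m, sigma)
  den <- .gaussSmooth(m, sigma)
  out <- a
  inside <- mask & den > 0
  out[inside] <- num[inside] / den[inside]
  out
}

# Physical coordinates (um) of voxel centres along one axis: index i
# (1-based) sits at (i - 1) * spacing.
.axisCoords <- function(n, spacing) (seq_len(n) - 1) * spacing

# Quick CSV writers/readers used by every table-producing stage.
.writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.readCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Column schema of the morphometric record table.
.morphRecordCols <- c("genotype", "timepoint_d", "height_um", "width_um",
                      "area_um2", "primordium_identity", "experiment_id")

.primordiumIdentities <- c("vegetative", "cauline", "floral")

# Validate a MorphRecord data.frame (see writeTable()).
.checkMorphRecords <- function(df) {
  miss <- setdiff(.morphRecordCols, names(df))
  if (length(miss))
    stop("morphometric table lacks columns: ", paste(miss, collapse = ", "))
  if (any(df$height_um <= 0 | df$width_um <= 0, na.rm = TRUE))
    stop("heights and widths must be positive")
  bad <- !df$primordium_identity %in% .primordiumIdentities
  if (any(bad))
    stop("unknown primordium identity: ",
         paste(unique(df$primordium_identity[bad]), collapse = ", "))
  invisible(df)
}
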