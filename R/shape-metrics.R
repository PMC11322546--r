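#' @include domain-quant.R
NULL

#' Measure SAM height and width in one orthogonal view
#'
#' Implements the landmark criteria: the width is the distance between
#' the two endpoints placed at the most apically visible primordium, and
#' the height is measured perpendicular to the width segment (so height
#' and width stay aligned with the apical-basal axis and orthogonal to
#' each other regardless of how the sample lies in the image). Landmarks
#' are explicit inputs in micrometres (or pixels with \code{pxUm} set):
#' the protocol step is manual, so the package takes the placed points
#' rather than auto-detecting them.
#'
#' @param apex numeric(2) apex landmark (u, w); w increases into the
#'   tissue (downward in the view)
#' @param end1,end2 numeric(2) width endpoints, distinct
#' @param view view label, e.g. "xz" or "yz"
#' @param pxUm scale factor applied to all landmark coordinates
#'   (micrometres per unit; 1 when landmarks are already in micrometres)
#' @return list with \code{view}, \code{height_um}, \code{width_um} and
#'   the landmarks used
#' @export
measureView <- function(apex, end1, end2, view = "xz", pxUm = 1) {
  apex <- apex * pxUm; end1 <- end1 * pxUm; end2 <- end2 * pxUm
  seg <- end2 - end1
  w <- sqrt(sum(seg^2))
  if (w == 0) stop("width endpoints must be distinct")
  # upward unit normal of the width line (pointing to smaller depth)
  nrm <- c(-seg[2L], seg[1L]) / w
  if (nrm[2L] > 0) nrm <- -nrm
  if (nrm[2L] == 0) stop("width segment is vertical; no apical side")
  h <- sum((apex - end1) * nrm)
  if (h <= 0) stop("apex lies below the width line (negative height)")
  list(view = view, height_um = h, width_um = w,
       landmarks = list(apex = apex, end1 = end1, end2 = end2))
}

#' Average the two orthogonal views of one meristem
#'
#' The two side views are technical replicates: the recorded height and
#' width are their arithmetic means. With a single usable view the values
#' pass through and the provenance notes it.
#'
#' @param v1 a view measurement from [measureView()]
#' @param v2 the orthogonal view, or \code{NULL} when unavailable
#' @param genotype,timepoint_d,primordium_identity,experiment_id
#'   annotation fields for the resulting record
#' @param area_um2 optional meristem area from [meristemArea()]
#' @return one-row data.frame in the morphometric record schema plus
#'   \code{n_views} and \code{provenance}
#' @export
mergeViews <- function(v1, v2 = NULL, genotype = NA_character_,
                       timepoint_d = NA_real_,
                       primordium_identity = "vegetative",
                       experiment_id = NA_character_,
                       area_um2 = NA_real_) {
  if (is.null(v2)) {
    h <- v1$height_um; w <- v1$width_um
    prov <- sprintf("single view (%s) only", v1$view)
    nv <- 1L
  } else {
    h <- mean(c(v1$height_um, v2$height_um))
    w <- mean(c(v1$width_um, v2$width_um))
    prov <- "mean of two orthogonal views"
    nv <- 2L
  }
  data.frame(genotype = genotype, timepoint_d = timepoint_d,
             height_um = h, width_um = w, area_um2 = area_um2,
             primordium_identity = primordium_identity,
             experiment_id = experiment_id, n_views = nv,
             provenance = prov)
}

#' Canonical parabola representing one meristem's shape
#'
#' The downward parabola through the apex \code{(0, H)} and the width
#' endpoints \code{(+/- W/2, 0)}: \code{y(x) = H (1 - (2x / W)^2)}. Used
#' to draw meristem morphology, coloured by the identity of the primordia
#' formed at the periphery.
#'
#' @param heightUm meristem height H, micrometres (> 0)
#' @param widthUm meristem width W, micrometres (> 0)
#' @param identity primordium identity colour key ("vegetative",
#'   "cauline" or "floral")
#' @return list with \code{H}, \code{W}, polynomial
#'   \code{coefficients} (intercept and x^2 term), the evaluation
#'   function \code{f(x)}, the enclosed \code{area_um2 = 2 H W / 3} and
#'   the \code{identity}
#' @export
shapeParabola <- function(heightUm, widthUm, identity = "vegetative") {
  stopifnot(heightUm > 0, widthUm > 0,
            identity %in% .primordiumIdentities)
  H <- heightUm; W <- widthUm
  list(H = H, W = W,
       coefficients = c(intercept = H, x2 = -4 * H / W^2),
       f = function(x) H * (1 - (2 * x / W)^2),
       area_um2 = 2 * H * W / 3,
       identity = identity)
}

#' Meristem area from a segmentation cell table
#'
#' Sums the areas of the cells flagged as meristem members (the flag
#' comes from the external curvature-based segmentation) and reports the
#' member cell count.
#'
#' @param cells data.frame with columns \code{area_um2} (> 0) and
#'   \code{meristem_member} (logical)
#' @return list with \code{area_um2} and \code{cell_count}
#' @export
meristemArea <- function(cells) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1L,
            all(c("area_um2", "meristem_member") %in% names(cells)))
  if (any(cells$area_um2 <= 0)) stop("cell areas must be positive")
  m <- cells$meristem_member
  if (!any(m)) warning("no meristem member cells; area is 0")
  list(area_um2 = sum(cells$area_um2[m]), cell_count = sum(m))
}

#' Timepoint of maximum median height per genotype
#'
#' For each genotype (and experiment, when present) selects the timepoint
#' whose median height is largest; ties break toward the earlier
#' timepoint. Used to pick the peak-height stage for cross-genotype
#' normalised comparisons.
#'
#' @param records morphometric record data.frame
#' @return data.frame with one row per genotype (x experiment):
#'   \code{genotype}, \code{experiment_id}, \code{timepoint_d},
#'   \code{median_height_um}
#' @export
maxHeightTimepoint <- function(records) {
  .checkMorphRecords(records)
  sp <- split(records, list(records$genotype, records$experiment_id),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    med <- tapply(g$height_um, g$timepoint_d, stats::median)
    tps <- as.numeric(names(med))
    ord <- order(-med, tps)
    data.frame(genotype = g$genotype[1L],
               experiment_id = g$experiment_id[1L],
               timepoint_d = tps[ord[1L]],
               median_height_um = unname(med[ord[1L]]))
  }))
  rownames(out) <- NULL
  out
}
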