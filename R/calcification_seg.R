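# Calcification detection. Calcium absorbs far more than contrasted blood,
# so calcifications sit above an adaptive threshold computed from the mean
# lumen HU. The search is confined to a ring around the aortic wall
# (dilation minus erosion of the wall mask, slice-wise), and the
# thresholding is done in raw Hounsfield units, not windowed gray, since
# calcium saturates the display LUT.

#' Calcification detection parameters
#'
#' @param ring_radius structuring radius in voxels for the dilate/erode
#'   pair building the ring (default 3 voxels, about 2.4 mm at typical
#'   pixel sizes — the scale of the aortic wall).
#' @param factor multiplicative constant > 1 applied to the mean lumen HU
#'   to form the threshold.
#' @param wall_source which mask approximates the aortic wall:
#'   \code{"thrombus"} (the combined lumen+thrombus region, default) or
#'   \code{"lumen"}.
#' @return A \code{CalcParams} object.
#' @export
calcParams <- function(ring_radius = 3L, factor = 1.5,
                       wall_source = c("thrombus", "lumen")) {
  wall_source <- match.arg(wall_source)
  ring_radius <- as.integer(ring_radius)
  if (ring_radius < 1L) stop("ring_radius must be >= 1", call. = FALSE)
  if (factor <= 1) stop("factor must be superior to one", call. = FALSE)
  structure(list(ring_radius = ring_radius, factor = factor,
                 wall_source = wall_source),
            class = "CalcParams")
}

#' @export
print.CalcParams <- function(x, ...) {
  cat(sprintf("CalcParams: ring radius %d vox, factor %g, wall = %s\n",
              x$ring_radius, x$factor, x$wall_source))
  invisible(x)
}

#' Ring-shaped working region around a wall mask
#'
#' Per slice, ring = dilate(wall, r) minus erode(wall, r) with a disc
#' structuring element of radius r; by construction the ring is disjoint
#' from the eroded wall interior.
#'
#' @param wall a [BinaryMask3D-class].
#' @param ring_radius radius in voxels.
#' @return A [BinaryMask3D-class] labelled "ring" (empty if the wall is
#'   empty).
#' @export
ringMask <- function(wall, ring_radius = 3L) {
  stopifnot(is(wall, "BinaryMask3D"))
  arr <- voxels(wall)
  dims <- dim(arr)
  out <- array(0L, dims)
  brush <- EBImage::makeBrush(2L * as.integer(ring_radius) + 1L,
                              shape = "disc")
  for (z in seq_len(dims[3])) {
    sl <- arr[, , z]
    if (!any(sl == 1L)) next
    d <- EBImage::dilate(sl, brush)
    e <- EBImage::erode(sl, brush)
    out[, , z] <- as.integer(d == 1 & e == 0)
  }
  BinaryMask3D(out, spacing(wall), "ring")
}

#' Adaptive calcification threshold from the lumen
#'
#' @param ct a [CTVolume-class].
#' @param lumen non-empty lumen mask.
#' @param factor constant > 1.
#' @return Threshold in HU: \code{factor * mean(HU over lumen voxels)}.
#' @export
calcThreshold <- function(ct, lumen, factor = 1.5) {
  stopifnot(is(ct, "CTVolume"))
  if (factor <= 1) stop("factor must be superior to one", call. = FALSE)
  lum <- .asMaskArray(lumen)
  if (!sum(lum)) stop("lumen mask is empty", call. = FALSE)
  if (!identical(dim(lum), dim(voxels(ct))))
    stop("lumen mask is not congruent with the CT volume", call. = FALSE)
  factor * mean(voxels(ct)[lum == 1L])
}

#' Segment calcifications in the wall ring
#'
#' Every voxel of the ring around the wall whose Hounsfield value exceeds
#' the adaptive threshold is a calcification.
#'
#' @param ct a [CTVolume-class].
#' @param wall wall mask (lumen or combined lumen+thrombus, per
#'   \code{params$wall_source} policy; passed explicitly here).
#' @param lumen lumen mask used for the adaptive threshold.
#' @param params a [calcParams()].
#' @param exclude optional mask removed from the search region. The
#'   pipeline passes the segmented spine (dilated by one voxel): cortical
#'   bone shares the calcium HU range, so wherever the aneurysm sac
#'   approaches a vertebra the wall ring would otherwise pick up bone.
#' @return A [BinaryMask3D-class] labelled "calcification"; the threshold
#'   used is attached as attribute \code{"threshold"}.
#' @export
segmentCalcifications <- function(ct, wall, lumen, params = calcParams(),
                                  exclude = NULL) {
  stopifnot(is(ct, "CTVolume"))
  .stopIfNotCongruent(ct, wall, "CT and wall mask")
  thr <- calcThreshold(ct, lumen, params$factor)
  ring <- voxels(ringMask(wall, params$ring_radius))
  calc <- (ring == 1L & voxels(ct) > thr) + 0L
  if (!is.null(exclude)) {
    ex <- .morphArr(.asMaskArray(exclude), .starOffsets3D(3L), TRUE)
    calc[ex == 1L] <- 0L
  }
  out <- BinaryMask3D(calc, spacing(ct), "calcification")
  attr(out, "threshold") <- thr
  out
}

#' Physical volume of a mask
#'
#' @param mask a [BinaryMask3D-class].
#' @return Volume in mm^3 (voxel count times dx*dy*dz).
#' @export
calcVolume <- function(mask) {
  stopifnot(is(mask, "BinaryMask3D"))
  sum(voxels(mask)) * prod(spacing(mask))
}
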