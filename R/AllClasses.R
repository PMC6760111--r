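#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib aortaseg, .registration = TRUE
NULL

MASK_LABELS <- c("lumen", "spine", "thrombus", "calcification", "ring", "wall", "generic")

.checkVolume <- function(object, range = NULL) {
  msg <- character()
  v <- object@voxels
  if (length(dim(v)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values (dx, dy, dz)")
  if (!is.null(range) && length(v) && (min(v) < range[1] || max(v) > range[2]))
    msg <- c(msg, sprintf("voxel values must lie in [%g, %g]", range[1], range[2]))
  if (length(msg)) msg else TRUE
}

#' CTVolume: a CT scan as a Hounsfield-unit voxel grid
#'
#' Container for raw CT data. Voxels are stored as a 3D array indexed
#' \code{[x, y, z]} where z is the cranio-caudal (body vertical) axis and +y
#' points posterior. Values are Hounsfield units (HU), clamped to the
#' conventional 12-bit CT range \[-1024, 3071\].
#'
#' @slot voxels 3D numeric array of HU values, dim (nx, ny, nz).
#' @slot spacing numeric(3), physical voxel size (dx, dy, dz) in mm.
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) .checkVolume(object, c(-1024, 3071)))

#' GrayVolume: windowed grayscale intensities in \[0, 255\]
#'
#' Product of the windowing LUT [applyWindow()]. Intensities are kept as
#' real numbers in \[0, 255\] (no 8-bit quantization); use [quantizeGray()]
#' for export.
#'
#' @slot voxels 3D numeric array of intensities in \[0, 255\].
#' @slot spacing numeric(3) voxel size in mm.
#' @export
setClass("GrayVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) .checkVolume(object, c(0, 255)))

#' BinaryMask3D: a segmentation mask congruent with its source volume
#'
#' @slot voxels 3D integer array of 0/1 values.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot label character, one of lumen, spine, thrombus, calcification,
#'   ring, wall or generic.
#' @export
setClass("BinaryMask3D",
  representation(voxels = "array", spacing = "numeric", label = "character"),
  validity = function(object) {
    msg <- .checkVolume(object)
    if (isTRUE(msg)) msg <- character()
    v <- object@voxels
    if (length(v) && !all(v == 0L | v == 1L))
      msg <- c(msg, "mask voxels must be exactly 0 or 1")
    if (length(object@label) != 1L || !object@label %in% MASK_LABELS)
      msg <- c(msg, paste("label must be one of:", paste(MASK_LABELS, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Construct a CTVolume
#' @param voxels 3D numeric array of Hounsfield units.
#' @param spacing numeric(3) voxel size (dx, dy, dz) in mm.
#' @return A [CTVolume-class] object.
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1)) {
  storage.mode(voxels) <- "double"
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a GrayVolume
#' @param voxels 3D numeric array with values in \[0, 255\].
#' @param spacing numeric(3) voxel size in mm.
#' @return A [GrayVolume-class] object.
#' @export
GrayVolume <- function(voxels, spacing = c(1, 1, 1)) {
  storage.mode(voxels) <- "double"
  new("GrayVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a BinaryMask3D
#' @param voxels 3D array coercible to 0/1 (logical accepted).
#' @param spacing numeric(3) voxel size in mm.
#' @param label mask label.
#' @return A [BinaryMask3D-class] object.
#' @export
BinaryMask3D <- function(voxels, spacing = c(1, 1, 1), label = "generic") {
  d <- dim(voxels)
  voxels <- as.integer(as.logical(voxels))
  dim(voxels) <- d
  new("BinaryMask3D", voxels = voxels, spacing = as.numeric(spacing),
      label = label)
}

#' Voxel array accessor
#' @param x a CTVolume, GrayVolume or BinaryMask3D.
#' @return The underlying 3D array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)
#' @rdname voxels
#' @export
setMethod("voxels", "GrayVolume", function(x) x@voxels)
#' @rdname voxels
#' @export
setMethod("voxels", "BinaryMask3D", function(x) x@voxels)

#' Physical voxel spacing accessor
#' @param x a volume object.
#' @return numeric(3), (dx, dy, dz) in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "CTVolume", function(x) x@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "GrayVolume", function(x) x@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "BinaryMask3D", function(x) x@spacing)

#' Mask label accessor
#' @param x a BinaryMask3D.
#' @return character label.
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' @rdname maskLabel
#' @export
setMethod("maskLabel", "BinaryMask3D", function(x) x@label)

.showVolume <- function(object, what, unit) {
  d <- dim(object@voxels)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              what, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  if (length(object@voxels))
    cat(sprintf("  %s range: [%.6g, %.6g]\n", unit,
                min(object@voxels), max(object@voxels)))
  invisible(NULL)
}

setMethod("show", "CTVolume", function(object)
  .showVolume(object, "CTVolume", "HU"))
setMethod("show", "GrayVolume", function(object)
  .showVolume(object, "GrayVolume", "intensity"))
setMethod("show", "BinaryMask3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("BinaryMask3D '%s': %d x %d x %d voxels, %d set (%.2f%%)\n",
              object@label, d[1], d[2], d[3], sum(object@voxels),
              100 * mean(object@voxels)))
  invisible(NULL)
})

# internal: congruence check between two volume-like objects
.stopIfNotCongruent <- function(a, b, what = "volumes") {
  if (!identical(dim(voxels(a)), dim(voxels(b))))
    stop(what, " have different grid shapes", call. = FALSE)
  if (max(abs(spacing(a) - spacing(b))) > 1e-6)
    stop(what, " have different voxel spacings", call. = FALSE)
  invisible(TRUE)
}
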