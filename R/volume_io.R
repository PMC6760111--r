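#' Window settings for the Hounsfield-to-grayscale LUT
#'
#' @param level window level L in HU (center of the displayed HU interval).
#' @param width window width W in HU (length of the interval); must be > 0.
#' @return A \code{WindowSettings} object.
#' @details The defaults (L = 40, W = 400) give a soft-tissue window adapted
#'   to contrast-enhanced lumen segmentation. For thrombus work the width is
#'   typically reduced to 300 or 200 to increase contrast.
#' @export
windowSettings <- function(level = 40, width = 400) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("window width W must be a single value > 0", call. = FALSE)
  structure(list(level = as.numeric(level), width = as.numeric(width)),
            class = "WindowSettings")
}

#' @export
print.WindowSettings <- function(x, ...) {
  cat(sprintf("WindowSettings: L = %g HU, W = %g HU\n", x$level, x$width))
  invisible(x)
}

#' Apply the windowing LUT to a CT volume
#'
#' Maps Hounsfield units H to grayscale intensities
#' \deqn{G = \min(255, \max(0, (H - (L - W/2)) \cdot 255 / W))}
#' where L is the window level and W the window width. Values are kept as
#' real numbers (no rounding to integers); see [quantizeGray()].
#'
#' @param ct a [CTVolume-class].
#' @param win a [windowSettings()] object (or NULL for the default L=40,
#'   W=400).
#' @return A [GrayVolume-class] with the same grid and spacing.
#' @export
applyWindow <- function(ct, win = windowSettings()) {
  stopifnot(is(ct, "CTVolume"))
  if (!inherits(win, "WindowSettings"))
    win <- do.call(windowSettings, as.list(win))
  v <- voxels(ct)
  g <- pmin(255, pmax(0, (v - (win$level - win$width / 2)) *
                           255 / win$width))
  dim(g) <- dim(v)
  GrayVolume(g, spacing(ct))
}

#' Quantize a GrayVolume to 8-bit integers
#'
#' Rounds half away from zero; intended for export and visualization only.
#' Segmentation operates on the real-valued grayscale.
#'
#' @param gray a [GrayVolume-class].
#' @return Integer 3D array in 0..255.
#' @export
quantizeGray <- function(gray) {
  stopifnot(is(gray, "GrayVolume"))
  v <- voxels(gray)
  q <- as.integer(floor(v + 0.5))
  dim(q) <- dim(v)
  q
}

#' Write a binary mask as NIfTI
#'
#' @param mask a [BinaryMask3D-class].
#' @param path output file (.nii or .nii.gz).
#' @return Invisibly, the path.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask3D"))
  img <- RNifti::asNifti(voxels(mask))
  RNifti::pixdim(img) <- spacing(mask)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file written by [writeMask()] (or any 0/1 volume).
#' @param label label to attach to the mask.
#' @param reference optional volume the mask must be congruent with; a
#'   shape or spacing mismatch is a hard error.
#' @return A [BinaryMask3D-class].
#' @export
readMask <- function(path, label = "generic", reference = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  m <- BinaryMask3D(array(as.integer(img != 0), dim = dim(img)[seq_len(3)]),
                    spacing = sp, label = label)
  if (!is.null(reference)) .stopIfNotCongruent(m, reference, "mask and reference")
  m
}

#' Write a CT volume as NIfTI
#' @param ct a [CTVolume-class].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeVolume <- function(ct, path) {
  stopifnot(is(ct, "CTVolume"))
  img <- RNifti::asNifti(voxels(ct))
  RNifti::pixdim(img) <- spacing(ct)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a CT volume from NIfTI (values interpreted as HU)
#' @param path NIfTI file.
#' @return A [CTVolume-class].
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  CTVolume(array(as.numeric(img), dim = dim(img)[seq_len(3)]), spacing = sp)
}
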