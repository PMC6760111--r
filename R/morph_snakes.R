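# Morphological active contours without edges (ACWE). The evolving surface
# is a binary voxel region; each iteration applies (i) a balloon force
# realized as binary dilation/erosion, (ii) a data-attachment update on the
# boundary band driven by the region means c1 (inside) and c2 (outside),
# and (iii) curvature-like smoothing built from the sup-of-erosions /
# inf-of-dilations operators over a family of discrete line segments,
# alternating E.D and D.E between iterations. Convergence is declared when
# the relative volume change dV/V drops below a tolerance.

#' ACWE snake parameters
#'
#' @param n_smooth number of smoothing passes per iteration (0-3). This is
#'   the discrete realization of the curvature weight: more passes give a
#'   smoother surface.
#' @param nu balloon weight; positive inflates (dilation), negative
#'   deflates (erosion), 0 disables. The magnitude is integerized as the
#'   number of morphological passes per iteration.
#' @param lambda_in,lambda_out data-attachment weights for the inside
#'   (lambda1) and outside (lambda2) intensity deviation terms; both
#'   nonnegative. Their quotient lambda_in/lambda_out is the weight ratio.
#' @param pattern_size structuring-pattern size, one of 3, 5, 7 (weak,
#'   medium, strong smoothing).
#' @param tol stopping tolerance on dV/V (default 1e-6).
#' @param max_iter iteration cap (150 suffices to discriminate aorta and
#'   arteries at lumen contrast).
#' @return A \code{SnakeParams} object.
#' @export
snakeParams <- function(n_smooth = 1L, nu = 1, lambda_in = 1,
                        lambda_out = 1, pattern_size = 3L,
                        tol = 1e-6, max_iter = 150L) {
  pattern_size <- as.integer(pattern_size)
  n_smooth <- as.integer(n_smooth)
  if (!pattern_size %in% c(3L, 5L, 7L))
    stop("pattern_size must be 3, 5 or 7", call. = FALSE)
  if (lambda_in < 0 || lambda_out < 0)
    stop("lambda weights must be nonnegative", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (n_smooth < 0L || n_smooth > 3L)
    stop("n_smooth must be between 0 and 3", call. = FALSE)
  structure(list(n_smooth = n_smooth, nu = nu, lambda_in = lambda_in,
                 lambda_out = lambda_out, pattern_size = pattern_size,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "SnakeParams")
}

#' @export
print.SnakeParams <- function(x, ...) {
  cat(sprintf(
    "SnakeParams: pattern %dx%d, n_smooth %d, nu %g, lambda %g/%g (WR %g), tol %g, max_iter %d\n",
    x$pattern_size, x$pattern_size, x$n_smooth, x$nu, x$lambda_in,
    x$lambda_out, x$lambda_in / x$lambda_out, x$tol, x$max_iter))
  invisible(x)
}

#' Binary erosion / dilation by the structuring pattern
#'
#' Erosion is the minimum and dilation the maximum of the mask over the
#' pattern neighbourhood (the union footprint of the four line segments:
#' the full 3x3 square for pattern 3, a star for 5 and 7). By default the
#' footprint is in-plane; \code{axial = TRUE} adds the two axial
#' neighbours so the operation can cross slices (used by the balloon
#' force).
#'
#' @param mask a [BinaryMask3D-class] or 3D 0/1 array.
#' @param pattern_size 3, 5 or 7.
#' @param axial include the +/-z neighbours in the footprint.
#' @return Same type as the input.
#' @export
erodeMask <- function(mask, pattern_size = 3L, axial = FALSE)
  .morphApply(mask, pattern_size, axial, dilate = FALSE)

#' @rdname erodeMask
#' @export
dilateMask <- function(mask, pattern_size = 3L, axial = FALSE)
  .morphApply(mask, pattern_size, axial, dilate = TRUE)

.morphApply <- function(mask, pattern_size, axial, dilate) {
  wrap <- is(mask, "BinaryMask3D")
  arr <- .asMaskArray(mask)
  off <- if (axial) .starOffsets3D(pattern_size) else
    .starOffsets2D(pattern_size)
  out <- .morphArr(arr, off, dilate)
  if (wrap) BinaryMask3D(out, spacing(mask), maskLabel(mask)) else out
}

# one smoothing operator application: S1 = E.D on even iterations,
# S2 = D.E on odd ones, where E is the sup of erosions and D the inf of
# dilations over the line family (slice-plane operators)
.smoothOnce <- function(arr, k, parity) {
  if (parity %% 2L == 0L) .supErosion(.infDilation(arr, k), k)
  else                    .infDilation(.supErosion(arr, k), k)
}

#' Morphological smoothing of a mask
#'
#' Applies the alternating smoothing operators S1 = E.D (even iterations)
#' and S2 = D.E (odd iterations) \code{n_smooth} times, where E and D are
#' the sup-of-erosions and inf-of-dilations over the four discrete line
#' segments of length \code{pattern_size}. \code{n_smooth = 0} is the
#' identity.
#'
#' @param mask a [BinaryMask3D-class] or 3D 0/1 array.
#' @param pattern_size 3, 5 or 7.
#' @param n_smooth number of passes.
#' @param iteration_parity which operator leads: even applies S1, odd S2.
#' @return Same type as the input.
#' @export
smoothMask <- function(mask, pattern_size = 3L, n_smooth = 1L,
                       iteration_parity = 0L) {
  wrap <- is(mask, "BinaryMask3D")
  arr <- .asMaskArray(mask)
  if (n_smooth > 0L)
    for (i in seq_len(n_smooth))
      arr <- .smoothOnce(arr, pattern_size, iteration_parity)
  if (wrap) BinaryMask3D(arr, spacing(mask), maskLabel(mask)) else arr
}

#' Region mean intensities inside and outside a mask
#'
#' @param image a [GrayVolume-class] (or 3D numeric array).
#' @param mask a congruent [BinaryMask3D-class] (or 0/1 array).
#' @return numeric(2): \code{c1} (mean inside), \code{c2} (mean outside).
#'   An empty region's mean is defined as 0, with a warning.
#' @export
regionMeans <- function(image, mask) {
  img <- if (is(image, "GrayVolume")) voxels(image) else image
  arr <- .asMaskArray(mask)
  if (!identical(dim(img), dim(arr)))
    stop("image and mask are not congruent", call. = FALSE)
  nIn <- sum(arr)
  nAll <- length(arr)
  sIn <- sum(img[arr == 1L])
  c1 <- if (nIn > 0) sIn / nIn else { warning("empty inside region"); 0 }
  c2 <- if (nAll > nIn) (sum(img) - sIn) / (nAll - nIn) else {
    warning("empty outside region"); 0
  }
  c(c1 = c1, c2 = c2)
}

# internal single ACWE iteration on raw arrays. Morphological proposals
# (balloon, smoothing) are gated by the data term: a flip is accepted only
# where it does not increase the data energy, so the region cannot flood
# through data-unsupported voxels that a large closing pattern adds away
# from the boundary band. Ties leave a voxel unchanged (a constant image
# is a fixed point).
.acweStepArr <- function(img, arr, params, iteration) {
  k <- params$pattern_size
  arr0 <- arr
  # (i) balloon force: unit (3-star, quasi-3D) structuring element, one
  # voxel of advance per pass — the pattern size scales the smoothing
  # strength only
  nballoon <- as.integer(abs(params$nu))
  if (nballoon > 0L) {
    off <- .starOffsets3D(3L)
    for (i in seq_len(nballoon))
      arr <- .morphArr(arr, off, params$nu > 0)
  }
  # (ii) data attachment, with means taken after the balloon so freshly
  # inflated voxels inform the inside mean; applied on the boundary band
  # plus every balloon-added voxel
  cm <- suppressWarnings(regionMeans(img, arr))
  off3 <- .starOffsets3D(3L)
  band <- which(.morphArr(arr, off3, TRUE) != .morphArr(arr, off3, FALSE) |
                  (arr == 1L & arr0 == 0L))
  if (length(band)) {
    d <- params$lambda_in * abs(img[band] - cm[1]) -
      params$lambda_out * abs(img[band] - cm[2])
    arr[band[d < 0]] <- 1L
    arr[band[d > 0]] <- 0L
  }
  preSmooth <- arr
  # (iii) smoothing, alternating S1/S2 with the iteration parity; voxels
  # the smoothing adds are vetoed where the data term strictly opposes
  if (params$n_smooth > 0L) {
    for (i in seq_len(params$n_smooth))
      arr <- .smoothOnce(arr, k, iteration + i - 1L)
    added <- which(arr == 1L & preSmooth == 0L)
    if (length(added)) {
      d <- params$lambda_in * abs(img[added] - cm[1]) -
        params$lambda_out * abs(img[added] - cm[2])
      arr[added[d > 0]] <- 0L
    }
  }
  attr(arr, "means") <- cm
  arr
}

#' One ACWE iteration
#'
#' Applies the balloon force, the data-attachment switch on the boundary
#' band (a voxel joins the region iff
#' \code{lambda_in * |I - c1| < lambda_out * |I - c2|}), and the
#' morphological smoothing, in that order.
#'
#' @param image a [GrayVolume-class].
#' @param mask current region as [BinaryMask3D-class].
#' @param params a [snakeParams()].
#' @param iteration iteration counter (controls S1/S2 alternation).
#' @return A list: \code{mask} (updated region), \code{volume} (voxel
#'   count), \code{dV} (absolute change), \code{c1}, \code{c2} (means
#'   that drove the step).
#' @export
acweStep <- function(image, mask, params = snakeParams(), iteration = 0L) {
  stopifnot(is(image, "GrayVolume"))
  arr0 <- .asMaskArray(mask)
  img <- voxels(image)
  if (!identical(dim(img), dim(arr0)))
    stop("image and mask are not congruent", call. = FALSE)
  arr <- .acweStepArr(img, arr0, params, iteration)
  cm <- attr(arr, "means")
  V <- sum(arr)
  if (V == 0L && params$nu <= 0)
    stop("collapsed region: the snake emptied and cannot re-inflate",
         call. = FALSE)
  list(mask = BinaryMask3D(arr, spacing(mask), maskLabel(mask)),
       volume = V, dV = abs(V - sum(arr0)), c1 = unname(cm[1]),
       c2 = unname(cm[2]))
}

#' Evolve an ACWE snake to convergence
#'
#' Iterates [acweStep()] until the relative volume change satisfies
#' \code{dV/V < tol} or \code{max_iter} is reached.
#'
#' @param image a [GrayVolume-class].
#' @param init non-empty initial region ([BinaryMask3D-class]).
#' @param params a [snakeParams()].
#' @return A list: \code{mask} (final region), \code{iterations} (number
#'   of steps applied), \code{converged} (logical).
#' @export
acweEvolve <- function(image, init, params = snakeParams()) {
  stopifnot(is(image, "GrayVolume"))
  arr <- .asMaskArray(init)
  if (!sum(arr)) stop("initial region is empty", call. = FALSE)
  img <- voxels(image)
  if (!identical(dim(img), dim(arr)))
    stop("image and init mask are not congruent", call. = FALSE)
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    prevV <- sum(arr)
    arr <- .acweStepArr(img, arr, params, iter)
    iter <- iter + 1L
    V <- sum(arr)
    if (V == 0L) {
      if (params$nu <= 0)
        stop("collapsed region: the snake emptied and cannot re-inflate",
             call. = FALSE)
    } else if (abs(V - prevV) / V < params$tol) {
      converged <- TRUE
      break
    }
  }
  list(mask = BinaryMask3D(arr, spacing(image),
                           maskLabel(init)),
       iterations = iter, converged = converged)
}

#' Automatic lumen initialization by axial extent
#'
#' Thresholds the volume, extracts 3D connected components (6-connected)
#' and returns the component with maximal z-extent — the contrasted aorta
#' is the longest vertical bright structure in an abdominal CT. The
#' process needs no user interaction.
#'
#' @param gray a [GrayVolume-class].
#' @param threshold intensity threshold in \[0, 255\].
#' @return A [BinaryMask3D-class] labelled "lumen".
#' @export
autoInitLumen <- function(gray, threshold = 200) {
  stopifnot(is(gray, "GrayVolume"))
  v <- voxels(gray)
  b <- (v >= threshold) + 0L
  dim(b) <- dim(v)
  if (!sum(b)) stop("no initial region: threshold leaves no voxels",
                    call. = FALSE)
  lab <- .label3dArr(b, 6L)
  ids <- seq_len(max(lab))
  zext <- vapply(ids, function(id) {
    zs <- which(apply(lab == id, 3, any))
    length(zs)
  }, integer(1))
  best <- which.max(zext)
  BinaryMask3D((lab == best) + 0L, spacing(gray), "lumen")
}

#' Weight-ratio / smoothing-count sweep
#'
#' Runs [acweEvolve()] over a grid of weight ratios (WR =
#' lambda_in/lambda_out, realized as lambda_in = WR, lambda_out = 1) and
#' smoothing counts, and reports the Dice similarity of each result
#' against the reference run (WR = 1, n_smooth = 0).
#'
#' @param image a [GrayVolume-class].
#' @param init initial region.
#' @param wr weight-ratio values (>= 1).
#' @param n_smooth smoothing-pass counts (0-3).
#' @param params base [snakeParams()] supplying the other fields.
#' @return data.frame with columns \code{wr}, \code{n_smooth},
#'   \code{dsc}.
#' @export
wrSmoothingSweep <- function(image, init, wr = c(1, 2, 5),
                             n_smooth = 0:3, params = snakeParams()) {
  runOne <- function(w, n) {
    p <- params
    p$lambda_in <- w; p$lambda_out <- 1; p$n_smooth <- as.integer(n)
    acweEvolve(image, init, p)$mask
  }
  ref <- runOne(1, 0)
  grid <- expand.grid(wr = wr, n_smooth = n_smooth)
  grid$dsc <- mapply(function(w, n) {
    if (w == 1 && n == 0) return(1)
    diceCoefficient(ref, runOne(w, n))
  }, grid$wr, grid$n_smooth)
  grid
}
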