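#' Denoising filter specification
#'
#' @param method one of \code{"median"}, \code{"gaussian"},
#'   \code{"bilateral"}, \code{"nlmeans"} or \code{"none"}.
#' @param size odd window size >= 3 (median, bilateral, and the nlmeans
#'   patch).
#' @param sigma gaussian kernel standard deviation in pixels.
#' @param sigma_spatial,sigma_range bilateral spatial and intensity
#'   standard deviations (pixels / gray levels).
#' @param strength nlmeans filtering strength h (gray levels).
#' @param search odd nlmeans search-window size.
#' @return A \code{FilterSpec} object.
#' @details The pipeline default is a median filter of window 3, the best
#'   compromise between noise suppression and speed for CT slices. All
#'   filtering is 2D, applied slice by slice, with reflect padding at the
#'   image border.
#' @export
filterSpec <- function(method = c("median", "gaussian", "bilateral",
                                  "nlmeans", "none"),
                       size = 3L, sigma = 1.0,
                       sigma_spatial = 1.5, sigma_range = 25,
                       strength = 10, search = 7L) {
  method <- match.arg(method)
  size <- as.integer(size); search <- as.integer(search)
  if (size < 3L || size %% 2L == 0L)
    stop("filter window size must be odd and >= 3", call. = FALSE)
  if (search < 3L || search %% 2L == 0L)
    stop("search window must be odd and >= 3", call. = FALSE)
  if (sigma <= 0 || sigma_spatial <= 0 || sigma_range <= 0 || strength <= 0)
    stop("filter sigmas and strength must be > 0", call. = FALSE)
  structure(list(method = method, size = size, sigma = sigma,
                 sigma_spatial = sigma_spatial, sigma_range = sigma_range,
                 strength = strength, search = search),
            class = "FilterSpec")
}

#' @export
print.FilterSpec <- function(x, ...) {
  cat("FilterSpec:", x$method,
      switch(x$method,
             median = sprintf("(window %d)", x$size),
             gaussian = sprintf("(sigma %g)", x$sigma),
             bilateral = sprintf("(window %d, sigma_s %g, sigma_r %g)",
                                 x$size, x$sigma_spatial, x$sigma_range),
             nlmeans = sprintf("(h %g, patch %d, search %d)",
                               x$strength, x$size, x$search),
             ""), "\n")
  invisible(x)
}

.gaussKernel1D <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

.convSep2D <- function(m, k) {
  h <- (length(k) - 1L) %/% 2L
  p <- .padReflect(m, h)
  # separable convolution: rows then columns
  p <- apply(p, 2, function(col) stats::filter(col, k, sides = 2))
  p <- t(apply(p, 1, function(row) stats::filter(row, k, sides = 2)))
  p[(h + 1):(nrow(p) - h), (h + 1):(ncol(p) - h)]
}

.shiftPad <- function(p, dx, dy, h, nx, ny) {
  p[(h + 1 + dx):(h + nx + dx), (h + 1 + dy):(h + ny + dy), drop = FALSE]
}

.medianSlice <- function(m, size) {
  # EBImage's constant-time median filter operates on [0,1] grayscale
  r <- (size - 1L) %/% 2L
  h <- r + 1L
  p <- .padReflect(m, h)
  f <- EBImage::medianFilter(p / 255, r)
  255 * f[(h + 1):(h + nrow(m)), (h + 1):(h + ncol(m))]
}

.bilateralSlice <- function(m, size, ss, sr) {
  h <- (size - 1L) %/% 2L
  p <- .padReflect(m, h)
  nx <- nrow(m); ny <- ncol(m)
  acc <- matrix(0, nx, ny); wacc <- matrix(0, nx, ny)
  for (dx in -h:h) for (dy in -h:h) {
    s <- .shiftPad(p, dx, dy, h, nx, ny)
    w <- exp(-(dx^2 + dy^2) / (2 * ss^2)) * exp(-(s - m)^2 / (2 * sr^2))
    acc <- acc + w * s
    wacc <- wacc + w
  }
  acc / wacc
}

.boxSum <- function(m, r) {
  # (2r+1)^2 moving-window sum with reflect padding, via cumulative sums
  h <- r
  p <- .padReflect(m, h)
  cs <- apply(p, 2, cumsum)
  cs <- rbind(0, cs)
  colsum <- cs[(2 * h + 2):nrow(cs), , drop = FALSE] -
            cs[seq_len(nrow(cs) - 2 * h - 1), , drop = FALSE]
  cs2 <- t(apply(colsum, 1, cumsum))
  cs2 <- cbind(0, cs2)
  cs2[, (2 * h + 2):ncol(cs2), drop = FALSE] -
    cs2[, seq_len(ncol(cs2) - 2 * h - 1), drop = FALSE]
}

.nlmeansSlice <- function(m, patch, search, strength) {
  pr <- (patch - 1L) %/% 2L
  sr <- (search - 1L) %/% 2L
  h <- sr
  p <- .padReflect(m, h)
  nx <- nrow(m); ny <- ncol(m)
  acc <- matrix(0, nx, ny); wacc <- matrix(0, nx, ny)
  npx <- patch^2
  for (dx in -sr:sr) for (dy in -sr:sr) {
    s <- .shiftPad(p, dx, dy, h, nx, ny)
    d2 <- .boxSum((s - m)^2, pr) / npx
    w <- exp(-pmax(d2 - 2 * strength^2, 0) / strength^2)
    acc <- acc + w * s
    wacc <- wacc + w
  }
  acc / wacc
}

#' Denoise a grayscale volume slice by slice
#'
#' Applies the 2D filter described by \code{spec} to every axial slice.
#' Output values are clamped back to \[0, 255\]; \code{method = "none"}
#' is the identity.
#'
#' @param vol a [GrayVolume-class].
#' @param spec a [filterSpec()].
#' @return A denoised [GrayVolume-class] on the same grid.
#' @export
denoiseVolume <- function(vol, spec = filterSpec()) {
  stopifnot(is(vol, "GrayVolume"))
  if (!inherits(spec, "FilterSpec"))
    stop("spec must be a FilterSpec", call. = FALSE)
  if (spec$method == "none") return(vol)
  v <- voxels(vol)
  k <- if (spec$method == "gaussian") .gaussKernel1D(spec$sigma)
  out <- v
  for (z in seq_len(dim(v)[3])) {
    m <- v[, , z]
    out[, , z] <- switch(spec$method,
      median   = .medianSlice(m, spec$size),
      gaussian = .convSep2D(m, k),
      bilateral = .bilateralSlice(m, spec$size, spec$sigma_spatial,
                                  spec$sigma_range),
      nlmeans  = .nlmeansSlice(m, spec$size, spec$search, spec$strength))
  }
  out <- pmin(255, pmax(0, out))
  dim(out) <- dim(v)
  GrayVolume(out, spacing(vol))
}
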