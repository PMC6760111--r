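# In-slice contour extraction and a-priori shape scoring. Contours are the
# outer borders of 8-connected foreground components; holes (e.g. a dark
# thrombus pocket inside a candidate) are filled before any descriptor is
# computed, since the shape criteria describe solid vessel cross-sections.

#' Shape criteria for pruning lumen candidates
#'
#' Thresholds are in physical units (mm, mm^2) and are converted with the
#' voxel spacing at pruning time. Two presets are provided: restrictive
#' criteria to localize the aorta with no false positives, and permissive
#' criteria for propagation through the whole arterial tree.
#'
#' @param min_area,max_area cross-section area bounds in mm^2.
#' @param min_aspect minimum aspect ratio A = min(w, h) / max(w, h) of the
#'   minimum-area rotated enclosing rectangle, in (0, 1].
#' @param min_solidity minimum solidity S = a / ha (area over convex-hull
#'   area), in (0, 1].
#' @param max_contour_length maximum contour perimeter in mm (Inf to
#'   disable).
#' @param preset "restrictive" (aorta localization: area 175-2400 mm^2,
#'   aspect >= 0.75, solidity >= 0.9, perimeter <= 220 mm) or "permissive"
#'   (propagation: area 4-2400 mm^2, aspect >= 0.2, solidity >= 0.6, no
#'   length cap). Explicit arguments override the preset.
#' @return A \code{ShapeCriteria} object.
#' @export
shapeCriteria <- function(preset = c("restrictive", "permissive"),
                          min_area = NULL, max_area = NULL,
                          min_aspect = NULL, min_solidity = NULL,
                          max_contour_length = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "restrictive")
    list(min_area = 175, max_area = 2400, min_aspect = 0.75,
         min_solidity = 0.9, max_contour_length = 220)
  else
    list(min_area = 4, max_area = 2400, min_aspect = 0.2,
         min_solidity = 0.6, max_contour_length = Inf)
  for (f in names(def)) {
    v <- get(f)
    if (!is.null(v)) def[[f]] <- v
  }
  if (def$min_area >= def$max_area)
    stop("min_area must be < max_area", call. = FALSE)
  if (def$min_aspect < 0 || def$min_aspect > 1 ||
      def$min_solidity < 0 || def$min_solidity > 1)
    stop("aspect/solidity thresholds must lie in [0, 1]", call. = FALSE)
  structure(def, class = "ShapeCriteria")
}

#' @export
print.ShapeCriteria <- function(x, ...) {
  cat(sprintf(
    "ShapeCriteria: area [%g, %g] mm^2, aspect >= %g, solidity >= %g, perimeter <= %g mm\n",
    x$min_area, x$max_area, x$min_aspect, x$min_solidity,
    x$max_contour_length))
  invisible(x)
}

#' Threshold one grayscale slice
#'
#' @param slice 2D numeric matrix of intensities.
#' @param threshold intensity in \[0, 255\]; a pixel is foreground iff
#'   G >= threshold.
#' @return Integer 0/1 matrix.
#' @export
binarizeSlice <- function(slice, threshold) {
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]", call. = FALSE)
  b <- (slice >= threshold) + 0L
  dim(b) <- dim(slice)
  b
}

.traceBoundary <- function(lab, id) {
  # outer-border following (Moore neighbourhood, clockwise) of component id
  idx <- which(lab == id, arr.ind = TRUE)
  start <- idx[order(idx[, 2], idx[, 1])[1], ]  # topmost-leftmost pixel
  nbr <- matrix(c(1L, 0L, 1L, 1L, 0L, 1L, -1L, 1L, -1L, 0L, -1L, -1L,
                  0L, -1L, 1L, -1L), ncol = 2, byrow = TRUE)
  nx <- nrow(lab); ny <- ncol(lab)
  inside <- function(x, y) x >= 1 && x <= nx && y >= 1 && y <= ny &&
    lab[x, y] == id
  pts <- matrix(start, 1, 2)
  if (sum(lab == id) == 1L) return(pts)
  dir <- 7L  # start search from "up-right" relative to entry from the left
  cur <- start
  repeat {
    found <- FALSE
    for (i in 0:7) {
      d <- (dir + i) %% 8L
      cand <- cur + nbr[d + 1L, ]
      if (inside(cand[1], cand[2])) {
        pts <- rbind(pts, cand)
        dir <- (d + 6L) %% 8L  # back up two directions
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break                       # isolated pixel
    if (all(cur == start) && nrow(pts) > 2L) break
  }
  if (nrow(pts) > 1L && all(pts[nrow(pts), ] == pts[1, ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

#' Find the outer contours of a binary slice
#'
#' One contour per 8-connected foreground component; holes are filled, so
#' each contour carries the solid member-pixel set of its component.
#'
#' @param binary integer/logical 2D matrix.
#' @param slice_index axial index recorded in each contour.
#' @return A list of \code{Contour2D} objects, each with fields
#'   \code{slice} (z index), \code{points} (ordered boundary polygon,
#'   pixel-center coordinates), \code{pixels} (member pixel indices) and
#'   \code{npix} (filled area in pixels).
#' @export
findContours <- function(binary, slice_index = 1L) {
  b <- (binary != 0) + 0L
  if (!sum(b)) return(list())
  arr <- array(as.integer(b), dim = c(dim(b), 1L))
  lab <- .label3dArr(arr, 26L)[, , 1]          # 8-connectivity in 2D
  lab <- EBImage::fillHull(lab)
  ids <- sort(unique(lab[lab > 0]))
  lapply(ids, function(id) {
    pts <- .traceBoundary(lab, id)
    pix <- which(lab == id, arr.ind = TRUE)
    structure(list(slice = as.integer(slice_index),
                   points = unname(pts), pixels = unname(pix),
                   npix = nrow(pix)),
              class = "Contour2D")
  })
}

#' @export
print.Contour2D <- function(x, ...) {
  cat(sprintf("Contour2D: slice %d, %d boundary points, %d pixels\n",
              x$slice, nrow(x$points), x$npix))
  invisible(x)
}

.shoelace <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

.minAreaRect <- function(hull) {
  # rotating calipers over the convex hull: the minimum-area enclosing
  # rectangle has a side collinear with a hull edge
  n <- nrow(hull)
  if (n < 2) return(c(0, 0))
  best <- c(Inf, 0, 0)
  for (i in seq_len(n)) {
    p1 <- hull[i, ]; p2 <- hull[if (i == n) 1L else i + 1L, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    w <- max(pu) - min(pu); h <- max(pv) - min(pv)
    if (w * h < best[1]) best <- c(w * h, w, h)
  }
  best[2:3]
}

# pixels (centers) lying inside or on the convex hull of a pixel set:
# the rasterized hull, so solidity compares like with like (pixel counts)
.hullPixelCount <- function(pix) {
  h <- grDevices::chull(pix)
  hull <- pix[h, , drop = FALSE]
  n <- nrow(hull)
  if (n < 3) return(nrow(unique(pix)))
  xs <- seq(min(pix[, 1]), max(pix[, 1]))
  ys <- seq(min(pix[, 2]), max(pix[, 2]))
  PX <- rep(xs, times = length(ys))
  PY <- rep(ys, each = length(xs))
  inside <- rep(TRUE, length(PX))
  for (i in seq_len(n)) {
    p1 <- hull[i, ]; p2 <- hull[if (i == n) 1L else i + 1L, ]
    # chull returns vertices clockwise: interior is to the right of each edge
    cr <- (p2[1] - p1[1]) * (PY - p1[2]) - (p2[2] - p1[2]) * (PX - p1[1])
    inside <- inside & cr <= 1e-9
    if (!any(inside)) break
  }
  sum(inside)
}

#' Shape descriptors of a contour
#'
#' Computes the solid area \code{a} (member pixels), convex-hull area
#' \code{ha}, the width/height of the minimum-area rotated enclosing
#' rectangle, and the derived aspect \code{A = min(w,h)/max(w,h)} and
#' solidity \code{S = a/ha}. The hull area is the rasterized hull (count
#' of pixels inside the convex hull of the member pixels), so solidity
#' compares pixel counts with pixel counts: a rasterized convex shape
#' scores S ~ 1 at any size. Width and height come from the minimum-area
#' rotated rectangle over pixel corner points (each boundary pixel
#' contributes its four corners), so a w x h pixel rectangle measures
#' exactly w x h.
#'
#' @param contour a \code{Contour2D} from [findContours()].
#' @return A list with fields \code{area}, \code{hull_area}, \code{w},
#'   \code{h}, \code{aspect}, \code{solidity}, \code{perimeter} (pixel
#'   units).
#' @export
shapeDescriptors <- function(contour) {
  if (!inherits(contour, "Contour2D"))
    stop("contour must be a Contour2D", call. = FALSE)
  if (is.null(contour$npix) || contour$npix < 1L)
    stop("degenerate contour: no member pixels", call. = FALSE)
  bp <- unique(contour$points)
  corners <- rbind(
    cbind(bp[, 1] - 0.5, bp[, 2] - 0.5), cbind(bp[, 1] + 0.5, bp[, 2] - 0.5),
    cbind(bp[, 1] - 0.5, bp[, 2] + 0.5), cbind(bp[, 1] + 0.5, bp[, 2] + 0.5))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  if (nrow(hull) < 3)
    stop("degenerate contour: collinear boundary", call. = FALSE)
  ha <- .hullPixelCount(contour$pixels)
  wh <- .minAreaRect(hull)
  p <- contour$points
  per <- if (nrow(p) > 1) {
    d <- p[c(2:nrow(p), 1), , drop = FALSE] - p
    sum(sqrt(rowSums(d^2)))
  } else 4  # single pixel: its square outline
  list(area = contour$npix, hull_area = ha,
       w = wh[1], h = wh[2],
       aspect = min(wh) / max(wh), solidity = min(1, contour$npix / ha),
       perimeter = per)
}

.descOf <- function(contour) {
  if (is.null(contour$desc)) shapeDescriptors(contour) else contour$desc
}

#' Prune contour candidates with physical shape criteria
#'
#' Keeps a contour iff its physical area lies within
#' \[min_area, max_area\] mm^2, aspect >= min_aspect, solidity >=
#' min_solidity and perimeter <= max_contour_length mm. Contours of fewer
#' than 3 pixels (noise specks below any vessel scale) are dropped
#' silently before scoring.
#'
#' @param contours list of \code{Contour2D}.
#' @param criteria a [shapeCriteria()].
#' @param spacing numeric(3) voxel spacing in mm.
#' @return The kept contours, each with its descriptors cached in
#'   \code{$desc}.
#' @export
pruneCandidates <- function(contours, criteria, spacing = c(1, 1, 1)) {
  if (!inherits(criteria, "ShapeCriteria"))
    stop("criteria must be a ShapeCriteria", call. = FALSE)
  keep <- list()
  pxArea <- spacing[1] * spacing[2]
  for (cn in contours) {
    if (cn$npix < 3L) next
    d <- .descOf(cn)
    areaMM <- d$area * pxArea
    if (areaMM < criteria$min_area || areaMM > criteria$max_area) next
    if (d$aspect < criteria$min_aspect) next
    if (d$solidity < criteria$min_solidity) next
    if (d$perimeter * spacing[1] > criteria$max_contour_length) next
    cn$desc <- d
    keep[[length(keep) + 1L]] <- cn
  }
  keep
}

.pixelKeys <- function(pix, nx = 100000L) {
  pix[, 1] + as.numeric(nx) * pix[, 2]
}

#' Overlap test between contours on adjacent slices
#'
#' @param c1,c2 \code{Contour2D} objects on axially adjacent slices.
#' @param min_overlap minimum number of shared pixels (projected on the
#'   same in-plane grid) required to call them intersecting.
#' @return TRUE iff the filled regions share at least \code{min_overlap}
#'   pixels.
#' @export
contoursIntersect <- function(c1, c2, min_overlap = 1L) {
  if (abs(c1$slice - c2$slice) != 1L)
    stop("contours must lie on adjacent slices", call. = FALSE)
  .contourOverlap(c1, c2) >= min_overlap
}

.contourOverlap <- function(c1, c2) {
  length(intersect(.pixelKeys(c1$pixels), .pixelKeys(c2$pixels)))
}
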