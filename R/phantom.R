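# Deterministic synthetic abdominal CT phantoms with ground truth. The
# phantom emulates the intensity structure the pipeline assumes: a bright
# contrasted lumen following a smooth centerline with an aneurysmal bulge
# and iliac bifurcation, an intermediate-intensity thrombus annulus around
# the bulge, a posterior bony spine column with spiky (low-solidity)
# cross-section, paraspinal muscle columns (one abutting the aneurysm),
# and small very-bright calcification specks on the wall, over a fat
# background with additive Gaussian noise.

#' Phantom specification
#'
#' All geometry is in mm; the volume axes are (x, y, z) with +y posterior
#' and z cranio-caudal. Intensity defaults are clinically typical HU
#' plateaus: lumen 300, thrombus 40, muscle 45, fat -80, bone 700,
#' calcification 900, noise sigma 15 HU.
#'
#' @param shape integer(3) grid size (nx, ny, nz).
#' @param spacing numeric(3) voxel size in mm.
#' @param seed RNG seed; the same spec generates bit-identical volumes.
#' @param lumen_hu,thrombus_hu,fat_hu,muscle_hu,bone_hu,calc_hu tissue
#'   plateaus in HU.
#' @param lumen_hu_end if non-NULL, the lumen HU tapers linearly from
#'   \code{lumen_hu} (cranial) to this value (caudal) — a poorly applied
#'   contrast bolus.
#' @param noise_sigma additive Gaussian noise standard deviation in HU.
#' @param aorta_radius baseline lumen radius (mm).
#' @param bulge_amp,bulge_sigma Gaussian radial enlargement of the lumen
#'   at the aneurysm (amplitude mm, axial sigma mm).
#' @param outer_amp,outer_sigma same for the outer (thrombus) wall.
#' @param bulge_center_frac axial position of the aneurysm center as a
#'   fraction of the volume height.
#' @param bif_frac axial position of the iliac bifurcation (fraction).
#' @param iliac_radius,iliac_slope iliac branch radius (mm) and lateral
#'   divergence per mm of depth.
#' @param curve_amp lateral amplitude of the smooth centerline curve (mm).
#' @param renal include renal branch stubs; \code{renal_frac} start depth
#'   fraction, \code{renal_radius} mm, \code{renal_drift} lateral mm per
#'   slice, \code{renal_len} slices.
#' @param spine include the spine; \code{spine_y} anterior-posterior
#'   center (mm), \code{spine_radius} vertebral body radius (mm).
#' @param muscle include paraspinal muscle columns; \code{muscle_offset}
#'   lateral offset, \code{muscle_y} center, \code{muscle_radius} mm.
#' @param calc_wall_count specks on the lumen wall (outside the bulge),
#'   \code{calc_outer_count} specks on the thrombus outer wall,
#'   \code{calc_radius} speck radius mm.
#' @param stent_band_frac if non-NULL, a 3-slice very-bright artifact band
#'   (metallic stent interference) is inserted at this depth fraction.
#' @param ring_gap if TRUE, a 30 degree arc of the thrombus outer border
#'   is erased from the image (painted as soft tissue); the ground-truth
#'   thrombus keeps the intact ring, so recovery of the erased arc can be
#'   measured.
#' @return A \code{PhantomSpec} object.
#' @export
phantomSpec <- function(shape = c(128L, 128L, 128L),
                        spacing = c(0.8, 0.8, 1.0),
                        seed = 7L,
                        lumen_hu = 300, thrombus_hu = 40, fat_hu = -80,
                        muscle_hu = 45, bone_hu = 700, calc_hu = 900,
                        lumen_hu_end = NULL,
                        noise_sigma = 15,
                        aorta_radius = 9, bulge_amp = 5, bulge_sigma = 12,
                        outer_amp = 13, outer_sigma = 14,
                        bulge_center_frac = 0.45,
                        bif_frac = 0.78, iliac_radius = 6,
                        iliac_slope = 0.36, curve_amp = 3,
                        renal = TRUE, renal_frac = 0.12,
                        renal_radius = 3.5, renal_drift = 1.5,
                        renal_len = 10L,
                        spine = TRUE, spine_y = 78, spine_radius = 12,
                        muscle = TRUE, muscle_offset = 28, muscle_y = 54,
                        muscle_radius = 9,
                        calc_wall_count = 3L, calc_outer_count = 3L,
                        calc_radius = 1.3,
                        stent_band_frac = NULL, ring_gap = FALSE) {
  stopifnot(length(shape) == 3L, all(shape >= 16),
            length(spacing) == 3L, all(spacing > 0),
            aorta_radius > 0, iliac_radius > 0, calc_radius > 0,
            noise_sigma >= 0)
  if (!(lumen_hu > thrombus_hu && thrombus_hu > fat_hu))
    stop("intensity ordering must satisfy lumen > thrombus > background",
         call. = FALSE)
  if (bone_hu < lumen_hu)
    stop("bone HU must be >= lumen HU", call. = FALSE)
  spec <- as.list(environment())
  spec$shape <- as.integer(shape)
  structure(spec, class = "PhantomSpec")
}

#' @export
print.PhantomSpec <- function(x, ...) {
  cat(sprintf(
    "PhantomSpec: %dx%dx%d @ %.2gx%.2gx%.2g mm, seed %d, noise sigma %g HU\n",
    x$shape[1], x$shape[2], x$shape[3], x$spacing[1], x$spacing[2],
    x$spacing[3], x$seed, x$noise_sigma))
  invisible(x)
}

#' Named phantom presets
#'
#' \describe{
#'   \item{ideal}{well-contrasted aorta surrounded by soft tissue, no
#'     artifacts — the easy scan.}
#'   \item{touching_spine}{the spine is moved anterior so that vertebral
#'     bone touches the aneurysm over many consecutive slices; exercises
#'     spine blackout.}
#'   \item{low_contrast}{the lumen contrast tapers from 300 to 150 HU
#'     toward the feet; a high propagation threshold stops the detection
#'     early (false negatives).}
#'   \item{stented_gap}{a 3-slice very-bright artifact band interrupts
#'     the aorta, emulating metallic stent-graft interference.}
#'   \item{ring_gap}{a 30 degree arc of the thrombus outer border is
#'     erased from the image; ground truth keeps the intact ring.}
#' }
#'
#' @param name preset name.
#' @param ... overrides forwarded to [phantomSpec()].
#' @return A \code{PhantomSpec}.
#' @export
phantomPreset <- function(name = c("ideal", "touching_spine", "stented_gap",
                                   "low_contrast", "ring_gap"), ...) {
  name <- match.arg(name)
  over <- switch(name,
    ideal = list(),
    touching_spine = list(spine_y = 66),
    low_contrast = list(lumen_hu_end = 150),
    stented_gap = list(stent_band_frac = 0.3),
    ring_gap = list(ring_gap = TRUE))
  do.call(phantomSpec, utils::modifyList(over, list(...)))
}

# lumen radius and outer (thrombus) wall radius profiles along z (mm)
.radiusProfiles <- function(spec, zmm) {
  zc <- spec$bulge_center_frac * max(zmm)
  rl <- spec$aorta_radius +
    spec$bulge_amp * exp(-((zmm - zc) / spec$bulge_sigma)^2)
  ro <- spec$aorta_radius +
    spec$outer_amp * exp(-((zmm - zc) / spec$outer_sigma)^2)
  list(lumen = rl, outer = pmax(ro, rl))
}

# deterministic calcification speck centers: (x, y, z) mm + radius
.calcCenters <- function(spec, xc, yc, zmm, prof) {
  zc <- spec$bulge_center_frac * max(zmm)
  zbif <- spec$bif_frac * max(zmm)
  out <- NULL
  wallAngles <- c(45, 150, 270) * pi / 180
  wallZ <- c(0.12, 0.18, 0.72) * max(zmm)
  for (i in seq_len(min(spec$calc_wall_count, 3L))) {
    zi <- which.min(abs(zmm - min(wallZ[i], zbif - 6)))
    r <- prof$lumen[zi]
    out <- rbind(out, c(xc[zi] + r * cos(wallAngles[i]),
                        yc[zi] + r * sin(wallAngles[i]), zmm[zi]))
  }
  outerAngles <- c(90, 180, 300) * pi / 180
  outerDz <- c(0, 6, -8)
  for (i in seq_len(min(spec$calc_outer_count, 3L))) {
    zi <- which.min(abs(zmm - (zc + outerDz[i])))
    r <- prof$outer[zi]
    out <- rbind(out, c(xc[zi] + r * cos(outerAngles[i]),
                        yc[zi] + r * sin(outerAngles[i]), zmm[zi]))
  }
  out
}

#' Generate a synthetic CT phantom with ground-truth masks
#'
#' Structures are voxelized analytically, painted with their HU plateau in
#' increasing priority order (background < muscle < spine < thrombus <
#' lumen < calcification), and Gaussian noise is added. Ground-truth
#' masks are the exact pre-noise voxel sets (for the \code{ring_gap}
#' preset the thrombus truth keeps the intact ring while the image holds
#' the erased arc). The same spec (including seed) generates bit-identical
#' output.
#'
#' @param spec a [phantomSpec()] or [phantomPreset()].
#' @return A list: \code{ct} ([CTVolume-class]), \code{truth} (list of
#'   [BinaryMask3D-class]: lumen, thrombus, spine, calcification),
#'   \code{spec}.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  sp <- spec$spacing
  xs <- seq_len(nx) * sp[1]
  ys <- seq_len(ny) * sp[2]
  zmm <- seq_len(nz) * sp[3]
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  x0 <- nx * sp[1] / 2
  y0 <- 42
  t <- (zmm - min(zmm)) / (max(zmm) - min(zmm))
  xc <- x0 + spec$curve_amp * sin(pi * t)
  yc <- rep(y0, nz)
  prof <- .radiusProfiles(spec, zmm)
  zbif <- spec$bif_frac * max(zmm)

  lumen <- array(FALSE, c(nx, ny, nz))
  thromb <- array(FALSE, c(nx, ny, nz))
  spine <- array(FALSE, c(nx, ny, nz))
  muscle <- array(FALSE, c(nx, ny, nz))
  gapArc <- array(FALSE, c(nx, ny, nz))

  renZ0 <- spec$renal_frac * max(zmm)
  for (z in seq_len(nz)) {
    dx2 <- (X - xc[z])^2
    d2 <- dx2 + (Y - yc[z])^2
    if (zmm[z] <= zbif) {
      sl <- d2 <= prof$lumen[z]^2
    } else {
      s <- spec$iliac_slope * (zmm[z] - zbif)
      sl <- ((X - (xc[z] - s))^2 + (Y - yc[z])^2 <= spec$iliac_radius^2) |
            ((X - (xc[z] + s))^2 + (Y - yc[z])^2 <= spec$iliac_radius^2)
    }
    if (spec$renal) {
      dz <- (zmm[z] - renZ0) / sp[3]
      if (dz >= 0 && dz < spec$renal_len) {
        off <- spec$renal_drift * dz
        sl <- sl |
          ((X - (xc[z] - off))^2 + (Y - yc[z])^2 <= spec$renal_radius^2) |
          ((X - (xc[z] + off))^2 + (Y - yc[z])^2 <= spec$renal_radius^2)
      }
    }
    lumen[, , z] <- sl
    if (zmm[z] <= zbif && prof$outer[z] > prof$lumen[z] + 0.3) {
      ring <- d2 <= prof$outer[z]^2 & !sl
      thromb[, , z] <- ring
      if (spec$ring_gap) {
        ang <- atan2(Y - yc[z], X - xc[z])
        deg <- (ang * 180 / pi) %% 360
        gapArc[, , z] <- ring & deg >= 15 & deg < 45 &
          d2 > (prof$outer[z] - 2.5)^2
      }
    }
    if (spec$spine) {
      body <- (X - x0)^2 + (Y - spec$spine_y)^2 <= spec$spine_radius^2
      post <- abs(X - x0) <= 3.5 & Y >= spec$spine_y &
        Y <= spec$spine_y + spec$spine_radius + 10
      trans <- abs(X - x0) <= 22 & abs(Y - (spec$spine_y - 2)) <= 2.5
      spine[, , z] <- body | post | trans
    }
    if (spec$muscle) {
      muscle[, , z] <-
        ((X - (x0 - spec$muscle_offset))^2 +
           (Y - spec$muscle_y)^2 <= spec$muscle_radius^2) |
        ((X - (x0 + spec$muscle_offset))^2 +
           (Y - spec$muscle_y)^2 <= spec$muscle_radius^2)
    }
  }

  calc <- array(FALSE, c(nx, ny, nz))
  centers <- .calcCenters(spec, xc, yc, zmm, prof)
  if (!is.null(centers)) {
    for (i in seq_len(nrow(centers))) {
      cz <- centers[i, 3]
      zr <- which(abs(zmm - cz) <= spec$calc_radius)
      for (z in zr) {
        r2 <- spec$calc_radius^2 - (zmm[z] - cz)^2
        calc[, , z] <- calc[, , z] |
          ((X - centers[i, 1])^2 + (Y - centers[i, 2])^2 <= r2)
      }
    }
  }

  # paint in increasing priority order
  vol <- array(spec$fat_hu, c(nx, ny, nz))
  vol[muscle] <- spec$muscle_hu
  vol[spine] <- spec$bone_hu
  vol[thromb] <- spec$thrombus_hu
  if (spec$ring_gap) vol[gapArc] <- 0       # soft tissue fills the erased arc
  lumenHU <- if (is.null(spec$lumen_hu_end)) rep(spec$lumen_hu, nz) else
    spec$lumen_hu + (spec$lumen_hu_end - spec$lumen_hu) * t
  for (z in seq_len(nz)) {
    slv <- vol[, , z]
    slv[lumen[, , z]] <- lumenHU[z]
    vol[, , z] <- slv
  }
  vol[calc] <- spec$calc_hu

  if (!is.null(spec$stent_band_frac)) {
    zi <- which.min(abs(zmm - spec$stent_band_frac * max(zmm)))
    for (z in zi:min(nz, zi + 2L)) {
      band <- (X - xc[z])^2 + (Y - yc[z])^2 <= 30^2
      slv <- vol[, , z]
      slv[band] <- 2000
      vol[, , z] <- slv
    }
  }

  vol <- .withSeed(spec$seed, {
    if (spec$noise_sigma > 0)
      vol + stats::rnorm(length(vol), 0, spec$noise_sigma)
    else vol
  })
  vol <- round(pmin(pmax(vol, -1024), 3071))
  dim(vol) <- c(nx, ny, nz)

  truthLumen <- lumen & !calc
  truthThromb <- thromb & !lumen & !calc
  truthSpine <- spine & !lumen & !thromb & !calc
  list(ct = CTVolume(vol, sp),
       truth = list(
         lumen = BinaryMask3D(truthLumen, sp, "lumen"),
         thrombus = BinaryMask3D(truthThromb, sp, "thrombus"),
         spine = BinaryMask3D(truthSpine, sp, "spine"),
         calcification = BinaryMask3D(calc, sp, "calcification")),
       spec = spec)
}
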