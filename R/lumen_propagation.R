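# Automatic aorta localization and arterial-tree segmentation by vertical
# contour propagation. Candidate contours are chained across consecutive
# slices where their filled regions intersect; the aorta is the longest
# chain under restrictive shape criteria, and the arterial system is then
# grown from it under permissive criteria. The spine is segmented first
# (same mechanism, bone threshold, low-solidity criteria) and blacked out,
# since vertebrae reach lumen-level intensities and touch the aorta.

#' Parameters for boundary-propagation lumen segmentation
#'
#' @param threshold lumen intensity threshold on the windowed \[0, 255\]
#'   scale. The default 200 robustly detects the contrasted arterial
#'   system with few false positives.
#' @param restrictive [shapeCriteria()] used to localize the aorta.
#' @param permissive [shapeCriteria()] used during propagation.
#' @param min_stack_length minimum chain length (slices) for a credible
#'   aorta.
#' @param min_overlap minimum shared pixels for two contours on adjacent
#'   slices to intersect.
#' @param jump_factor online error detection: a candidate whose area
#'   exceeds \code{jump_factor} times the area of the accepted neighbour
#'   contour it grows from is rejected (and counted). Set to Inf to
#'   disable.
#' @param spine_threshold bone-level intensity threshold for spine
#'   segmentation.
#' @param spine_max_solidity stacks whose mean solidity is below this are
#'   spine candidates (vertebrae are spiky; vessels are smooth).
#' @return A \code{PropagationParams} object.
#' @export
propagationParams <- function(threshold = 200,
                              restrictive = shapeCriteria("restrictive"),
                              permissive = shapeCriteria("permissive"),
                              min_stack_length = 10L,
                              min_overlap = 1L,
                              jump_factor = 3,
                              spine_threshold = 230,
                              spine_max_solidity = 0.85) {
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]", call. = FALSE)
  structure(list(threshold = threshold, restrictive = restrictive,
                 permissive = permissive,
                 min_stack_length = as.integer(min_stack_length),
                 min_overlap = as.integer(min_overlap),
                 jump_factor = jump_factor,
                 spine_threshold = spine_threshold,
                 spine_max_solidity = spine_max_solidity),
            class = "PropagationParams")
}

# per-slice pruned candidate contours of a gray array
.sliceCandidates <- function(grayArr, threshold, criteria, spacing) {
  nz <- dim(grayArr)[3]
  lapply(seq_len(nz), function(z) {
    pruneCandidates(findContours(binarizeSlice(grayArr[, , z], threshold),
                                 slice_index = z),
                    criteria, spacing)
  })
}

.newStack <- function(contour) {
  structure(list(contours = stats::setNames(list(contour),
                                            as.character(contour$slice)),
                 slices = contour$slice),
            class = "ContourStack")
}

#' @export
print.ContourStack <- function(x, ...) {
  cat(sprintf("ContourStack: slices %d..%d (z-extent %d)\n",
              min(x$slices), max(x$slices), length(x$slices)))
  invisible(x)
}

#' z-extent of a contour stack
#' @param stack a \code{ContourStack}.
#' @return Number of consecutive slices covered.
#' @export
stackExtent <- function(stack) length(stack$slices)

#' Chain candidate contours into vertical stacks
#'
#' Per slice: binarize, extract contours, prune with \code{criteria};
#' then chain contours across consecutive slices wherever their filled
#' regions intersect. Chaining is greedy in slice order with deterministic
#' tie-breaks (largest pixel overlap, then larger candidate area); each
#' contour belongs to at most one stack.
#'
#' @param gray a [GrayVolume-class].
#' @param threshold intensity threshold in \[0, 255\].
#' @param criteria a [shapeCriteria()].
#' @param min_overlap minimum shared pixels to link two contours.
#' @return List of \code{ContourStack} objects, longest first.
#' @export
buildStacks <- function(gray, threshold, criteria, min_overlap = 1L) {
  stopifnot(is(gray, "GrayVolume"))
  cand <- .sliceCandidates(voxels(gray), threshold, criteria, spacing(gray))
  stacks <- list()
  active <- integer(0)       # indices into `stacks` with a contour at z-1
  for (z in seq_along(cand)) {
    cz <- cand[[z]]
    if (!length(cz)) { active <- integer(0); next }
    links <- NULL
    for (si in active) {
      tail <- stacks[[si]]$contours[[as.character(z - 1L)]]
      for (ci in seq_along(cz)) {
        ov <- .contourOverlap(tail, cz[[ci]])
        if (ov >= min_overlap)
          links <- rbind(links, c(si, ci, ov, cz[[ci]]$npix))
      }
    }
    usedS <- integer(0); usedC <- integer(0)
    nowActive <- integer(0)
    if (!is.null(links)) {
      links <- links[order(-links[, 3], -links[, 4]), , drop = FALSE]
      for (r in seq_len(nrow(links))) {
        si <- links[r, 1]; ci <- links[r, 2]
        if (si %in% usedS || ci %in% usedC) next
        stacks[[si]]$contours[[as.character(z)]] <- cz[[ci]]
        stacks[[si]]$slices <- c(stacks[[si]]$slices, z)
        usedS <- c(usedS, si); usedC <- c(usedC, ci)
        nowActive <- c(nowActive, si)
      }
    }
    for (ci in setdiff(seq_along(cz), usedC)) {
      stacks[[length(stacks) + 1L]] <- .newStack(cz[[ci]])
      nowActive <- c(nowActive, length(stacks))
    }
    active <- nowActive
  }
  stacks[order(-vapply(stacks, stackExtent, integer(1)))]
}

.stackTotalArea <- function(stack)
  sum(vapply(stack$contours, function(cn) cn$npix, numeric(1)))

.stackMeanY <- function(stack)
  mean(vapply(stack$contours, function(cn) mean(cn$pixels[, 2]), numeric(1)))

.stackMeanSolidity <- function(stack)
  mean(vapply(stack$contours,
              function(cn) .descOf(cn)$solidity, numeric(1)))

#' Localize the aorta among contour stacks
#'
#' The aorta is the stack with maximal z-extent; ties are broken by larger
#' total filled area, then by the more posterior centroid (the aorta lies
#' immediately anterior to the spine, posterior to most other abdominal
#' structures).
#'
#' @param stacks list of \code{ContourStack} from [buildStacks()].
#' @param min_stack_length minimum acceptable z-extent.
#' @return The selected \code{ContourStack}.
#' @export
localizeAorta <- function(stacks, min_stack_length = 10L) {
  if (!length(stacks))
    stop("aorta not found: no contour stacks", call. = FALSE)
  ext <- vapply(stacks, stackExtent, integer(1))
  if (max(ext) < min_stack_length)
    stop("aorta not found: longest stack spans ", max(ext),
         " slices (< ", min_stack_length, ")", call. = FALSE)
  best <- which(ext == max(ext))
  if (length(best) > 1L) {
    areas <- vapply(stacks[best], .stackTotalArea, numeric(1))
    best <- best[areas == max(areas)]
    if (length(best) > 1L) {
      ys <- vapply(stacks[best], .stackMeanY, numeric(1))
      best <- best[which.max(ys)]
    }
  }
  stacks[[best[1]]]
}

.stackMask <- function(stack, dims) {
  m <- array(0L, dims)
  for (cn in stack$contours)
    m[cbind(cn$pixels, cn$slice)] <- 1L
  m
}

#' Segment the spine by boundary propagation
#'
#' Runs the same stack-building mechanism at a bone-level threshold with
#' spine-shaped criteria (any solidity, generous area range) and selects
#' the longest stack whose mean solidity is below
#' \code{spine_max_solidity} — vertebral cross-sections are spiky, vessel
#' cross-sections are smooth and convex. The selected stack's filled
#' regions are morphologically closed slice-wise to form the mask.
#'
#' @param gray a [GrayVolume-class].
#' @param params a [propagationParams()].
#' @return A [BinaryMask3D-class] labelled "spine" (empty if no
#'   spine-like structure is present).
#' @export
segmentSpine <- function(gray, params = propagationParams()) {
  stopifnot(is(gray, "GrayVolume"))
  crit <- shapeCriteria("permissive", min_area = 50, max_area = 8000,
                        min_aspect = 0.1, min_solidity = 0,
                        max_contour_length = Inf)
  stacks <- buildStacks(gray, params$spine_threshold, crit,
                        params$min_overlap)
  dims <- dim(voxels(gray))
  keep <- Filter(function(s)
    stackExtent(s) >= params$min_stack_length &&
      .stackMeanSolidity(s) < params$spine_max_solidity, stacks)
  if (!length(keep))
    return(BinaryMask3D(array(0L, dims), spacing(gray), "spine"))
  ext <- vapply(keep, stackExtent, integer(1))
  best <- which(ext == max(ext))
  if (length(best) > 1L) {
    areas <- vapply(keep[best], .stackTotalArea, numeric(1))
    best <- best[which.max(areas)]
  }
  m <- .stackMask(keep[[best[1]]], dims)
  brush <- EBImage::makeBrush(5, shape = "disc")
  for (z in seq_len(dims[3]))
    if (any(m[, , z] == 1L))
      m[, , z] <- as.integer(EBImage::closing(m[, , z], brush))
  BinaryMask3D(m, spacing(gray), "spine")
}

# zero out the (dilated) spine region of a gray array
.blackoutSpine <- function(grayArr, spine) {
  if (is.null(spine)) return(grayArr)
  sp <- .asMaskArray(spine)
  if (!sum(sp)) return(grayArr)
  sp <- .morphArr(sp, .starOffsets3D(3L), TRUE)
  grayArr[sp == 1L] <- 0
  grayArr
}

#' Propagate the arterial system from a seed aorta stack
#'
#' The spine mask (dilated by one voxel) is blacked out of the working
#' volume; per-slice candidate contours are recomputed under the
#' permissive criteria; and contours are accreted breadth-first from the
#' seed wherever a candidate intersects an already accepted contour on an
#' adjacent slice. Online error detection rejects any candidate whose
#' area exceeds \code{jump_factor} times the area of the contour it grows
#' from; the rejection count is returned in the \code{"rejected"}
#' attribute of the result.
#'
#' @param gray a [GrayVolume-class].
#' @param seed a \code{ContourStack} from [localizeAorta()].
#' @param params a [propagationParams()].
#' @param spine optional [BinaryMask3D-class] to black out (NULL to skip).
#' @return A [BinaryMask3D-class] labelled "lumen" covering the arterial
#'   system.
#' @export
propagateArterial <- function(gray, seed, params = propagationParams(),
                              spine = NULL) {
  stopifnot(is(gray, "GrayVolume"))
  grayArr <- .blackoutSpine(voxels(gray), spine)
  dims <- dim(grayArr)
  cand <- .sliceCandidates(grayArr, params$threshold, params$permissive,
                           spacing(gray))
  accepted <- lapply(seq_len(dims[3]), function(z) logical(length(cand[[z]])))
  queue <- list()
  rejected <- 0L
  # seed: permissive contours overlapping a seed contour on the same slice
  for (cn in seed$contours) {
    z <- cn$slice
    for (ci in seq_along(cand[[z]])) {
      if (accepted[[z]][ci]) next
      if (.contourOverlap(cn, cand[[z]][[ci]]) >= params$min_overlap) {
        accepted[[z]][ci] <- TRUE
        queue[[length(queue) + 1L]] <- c(z, ci)
      }
    }
  }
  while (length(queue)) {
    it <- queue[[1]]; queue <- queue[-1]
    z <- it[1]; ci <- it[2]
    cur <- cand[[z]][[ci]]
    for (zn in c(z - 1L, z + 1L)) {
      if (zn < 1L || zn > dims[3]) next
      for (cj in seq_along(cand[[zn]])) {
        if (accepted[[zn]][cj]) next
        nxt <- cand[[zn]][[cj]]
        if (.contourOverlap(cur, nxt) < params$min_overlap) next
        if (is.finite(params$jump_factor) &&
            nxt$npix > params$jump_factor * cur$npix) {
          rejected <- rejected + 1L
          next
        }
        accepted[[zn]][cj] <- TRUE
        queue[[length(queue) + 1L]] <- c(zn, cj)
      }
    }
  }
  m <- array(0L, dims)
  for (z in seq_len(dims[3]))
    for (ci in which(accepted[[z]]))
      m[cbind(cand[[z]][[ci]]$pixels, z)] <- 1L
  # the seed's own filled voxels are lumen by definition
  for (cn in seed$contours)
    m[cbind(cn$pixels, cn$slice)] <- 1L
  out <- BinaryMask3D(m, spacing(gray), "lumen")
  attr(out, "rejected") <- rejected
  out
}

#' Full boundary-propagation lumen segmentation
#'
#' Convenience wrapper: black out the spine, build restrictive stacks,
#' localize the aorta, then propagate permissively.
#'
#' @param gray a [GrayVolume-class].
#' @param params a [propagationParams()].
#' @param spine optional spine [BinaryMask3D-class]; if missing it is
#'   computed with [segmentSpine()]. Pass NULL to disable spine blackout.
#' @return A list with elements \code{lumen} (mask), \code{spine} (mask
#'   or NULL), \code{seed} (the aorta \code{ContourStack}).
#' @export
segmentLumen <- function(gray, params = propagationParams(),
                         spine = segmentSpine(gray, params)) {
  stopifnot(is(gray, "GrayVolume"))
  grayArr <- .blackoutSpine(voxels(gray), spine)
  work <- GrayVolume(grayArr, spacing(gray))
  stacks <- buildStacks(work, params$threshold, params$restrictive,
                        params$min_overlap)
  seed <- localizeAorta(stacks, params$min_stack_length)
  lumen <- propagateArterial(gray, seed, params, spine)
  list(lumen = lumen, spine = spine, seed = seed)
}

#' Threshold sensitivity sweep of the propagation method
#'
#' Runs the full propagation pipeline once per threshold and reports the
#' Dice similarity against a reference mask (typically phantom ground
#' truth). Thresholds at which the aorta cannot be localized report
#' DSC 0.
#'
#' @param gray a [GrayVolume-class].
#' @param thresholds numeric vector of thresholds in \[0, 255\].
#' @param reference a [BinaryMask3D-class] reference lumen.
#' @param params a [propagationParams()] (its threshold field is
#'   overridden per run).
#' @param spine optional spine mask shared across runs.
#' @return data.frame with columns \code{threshold}, \code{dsc}.
#' @export
thresholdSensitivitySweep <- function(gray, thresholds, reference,
                                      params = propagationParams(),
                                      spine = segmentSpine(gray, params)) {
  dsc <- vapply(thresholds, function(th) {
    p <- params; p$threshold <- th
    res <- tryCatch(segmentLumen(gray, p, spine), error = function(e) NULL)
    if (is.null(res)) return(0)
    diceCoefficient(reference, res$lumen)
  }, numeric(1))
  data.frame(threshold = thresholds, dsc = dsc)
}
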