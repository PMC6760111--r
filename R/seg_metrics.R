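# Segmentation evaluation metrics: overlap (Dice, Jaccard, sensitivity,
# specificity), volume (volumetric similarity) and surface distance
# (Hausdorff), plus per-slice surface series and their correlation.

#' Voxelwise confusion counts between two masks
#'
#' @param truth,pred congruent [BinaryMask3D-class] objects (or 0/1
#'   arrays); \code{truth} is the reference.
#' @return A list with fields \code{TP}, \code{FP}, \code{FN}, \code{TN}.
#' @export
confusionCounts <- function(truth, pred) {
  t <- .asMaskArray(truth); p <- .asMaskArray(pred)
  if (!identical(dim(t), dim(p)))
    stop("masks have different grid shapes", call. = FALSE)
  tp <- sum(t & p)
  list(TP = tp, FP = sum(p) - tp, FN = sum(t) - tp,
       TN = length(t) - sum(t | p))
}

.overlapCore <- function(a, b) {
  A <- .asMaskArray(a); B <- .asMaskArray(b)
  if (!identical(dim(A), dim(B)))
    stop("masks have different grid shapes", call. = FALSE)
  c(inter = sum(A & B), na = sum(A), nb = sum(B))
}

#' Dice similarity coefficient
#'
#' \code{DSC = 2 |R1 n R2| / (|R1| + |R2|)}: 0 for disjoint regions, 1
#' for complete overlap. Two empty regions compare as 1 (with a warning).
#'
#' @param r1,r2 congruent masks.
#' @return DSC in \[0, 1\].
#' @export
diceCoefficient <- function(r1, r2) {
  o <- .overlapCore(r1, r2)
  if (o["na"] + o["nb"] == 0) {
    warning("both regions empty; DSC defined as 1")
    return(1)
  }
  unname(2 * o["inter"] / (o["na"] + o["nb"]))
}

#' Jaccard index
#'
#' \code{JAC = TP / (TP + FP + FN)}, related to Dice by
#' \code{JAC = DSC / (2 - DSC)}.
#'
#' @param r1,r2 congruent masks.
#' @return JAC in \[0, 1\].
#' @export
jaccardIndex <- function(r1, r2) {
  o <- .overlapCore(r1, r2)
  den <- o["na"] + o["nb"] - o["inter"]
  if (den == 0) {
    warning("both regions empty; JAC defined as 1")
    return(1)
  }
  unname(o["inter"] / den)
}

#' Sensitivity, specificity and volumetric similarity from counts
#'
#' \code{Sensitivity = TP/(TP+FN)}, \code{Specificity = TN/(TN+FP)},
#' \code{VS = 1 - |FN-FP| / (2 TP + FP + FN)}. A metric whose denominator
#' is zero is reported as NA.
#'
#' @param counts result of [confusionCounts()].
#' @return Named numeric(3): sensitivity, specificity, vs.
#' @export
overlapRates <- function(counts) {
  sens <- if (counts$TP + counts$FN > 0)
    counts$TP / (counts$TP + counts$FN) else NA_real_
  spec <- if (counts$TN + counts$FP > 0)
    counts$TN / (counts$TN + counts$FP) else NA_real_
  vsDen <- 2 * counts$TP + counts$FP + counts$FN
  vs <- if (vsDen > 0) 1 - abs(counts$FN - counts$FP) / vsDen else NA_real_
  c(sensitivity = sens, specificity = spec, vs = vs)
}

#' Symmetric Hausdorff distance between two masks (mm)
#'
#' \code{HD(A, B) = max(h(A, B), h(B, A))} with
#' \code{h(A, B) = max_{a in A} min_{b in B} |a - b|}, Euclidean over
#' voxel-center coordinates scaled by the physical spacing. The directed
#' distances are evaluated on the voxels of each mask outside the other
#' against the 26-connectivity boundary of the other, which leaves the
#' value unchanged while keeping the computation tractable.
#'
#' @param a,b congruent non-empty masks.
#' @return Hausdorff distance in mm.
#' @export
hausdorffDistance <- function(a, b) {
  A <- .asMaskArray(a); B <- .asMaskArray(b)
  if (!identical(dim(A), dim(B)))
    stop("masks have different grid shapes", call. = FALSE)
  if (!sum(A) || !sum(B))
    stop("Hausdorff distance undefined for an empty mask", call. = FALSE)
  sp <- if (is(a, "BinaryMask3D")) spacing(a) else c(1, 1, 1)
  directed <- function(X, Y) {
    outside <- X
    outside[Y == 1L] <- 0L
    if (!sum(outside)) return(0)
    cpp_directed_hausdorff(.maskCoordsMM(outside, sp),
                           .maskCoordsMM(.boundaryArr(Y), sp))
  }
  max(directed(A, B), directed(B, A))
}

#' Per-slice cross-section surfaces of a mask
#'
#' @param mask a [BinaryMask3D-class].
#' @return data.frame with columns \code{z} (slice index) and
#'   \code{surface} (in-slice voxel count times dx*dy, mm^2).
#' @export
perSliceSurfaces <- function(mask) {
  stopifnot(is(mask, "BinaryMask3D"))
  arr <- voxels(mask)
  sp <- spacing(mask)
  data.frame(z = seq_len(dim(arr)[3]),
             surface = apply(arr, 3, sum) * sp[1] * sp[2])
}

#' Pearson correlation of two per-slice surface series
#'
#' Slices with zero surface in both series are excluded; fewer than 3
#' remaining paired slices give NA.
#'
#' @param surfA,surfB data.frames from [perSliceSurfaces()] on congruent
#'   volumes.
#' @return Pearson r, or NA if undefined.
#' @export
surfaceCorrelation <- function(surfA, surfB) {
  m <- merge(surfA, surfB, by = "z")
  m <- m[m$surface.x > 0 | m$surface.y > 0, ]
  if (nrow(m) < 3) return(NA_real_)
  stats::cor(m$surface.x, m$surface.y)
}

#' Full metric report comparing a prediction with ground truth
#'
#' @param truth,pred congruent [BinaryMask3D-class] objects.
#' @return A \code{MetricsReport}: dsc, jac, sensitivity, specificity,
#'   vs, hausdorff (mm) and the per-slice surfaces of both masks.
#' @export
evaluateSegmentation <- function(truth, pred) {
  .stopIfNotCongruent(truth, pred, "truth and prediction")
  counts <- confusionCounts(truth, pred)
  rates <- overlapRates(counts)
  hd <- if (sum(voxels(truth)) && sum(voxels(pred)))
    hausdorffDistance(truth, pred) else NA_real_
  structure(list(
    dsc = diceCoefficient(truth, pred),
    jac = jaccardIndex(truth, pred),
    sensitivity = unname(rates["sensitivity"]),
    specificity = unname(rates["specificity"]),
    vs = unname(rates["vs"]),
    hausdorff = hd,
    counts = counts,
    surfaces_truth = perSliceSurfaces(truth),
    surfaces_pred = perSliceSurfaces(pred)),
    class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport\n")
  cat(sprintf("  DSC %.4f  JAC %.4f  sens %.4f  spec %.4f  VS %.4f  HD %.3f mm\n",
              x$dsc, x$jac, x$sensitivity, x$specificity, x$vs,
              x$hausdorff))
  invisible(x)
}
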