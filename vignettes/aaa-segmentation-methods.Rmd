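---
title: "Automated AAA segmentation: models, parameters and design choices"
author: "aortaseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated AAA segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An abdominal aortic aneurysm (AAA) is a focal dilation of the infrarenal
aorta. On an arterial-phase contrast CT the blood-filled lumen is bright,
the intraluminal thrombus lining the aneurysm sac is of intermediate
intensity with poorly defined borders, wall calcifications are the
brightest structures in the image, and the adjacent vertebral bone
overlaps the lumen's intensity range. `aortaseg` implements a fully
automatic four-stage pipeline for this setting: preprocessing, lumen
segmentation, thrombus segmentation and calcification detection, plus the
evaluation metrics used to score each stage and a deterministic phantom
generator that provides ground truth.

All volumes are indexed `[x, y, z]` with z the cranio-caudal (body
vertical) axis and +y pointing posterior. Physical voxel spacing
travels with every object; shape criteria are expressed in mm and mm².

## Windowing

Grayscale intensities are produced from Hounsfield units by the linear
window LUT

$$G = \min\!\big(255,\ \max\!\big(0,\ (H - (L - W/2)) \cdot 255/W\big)\big)$$

with level $L$ and width $W$. The defaults are $L=40$, $W=400$ for lumen
work. $G$ is kept real-valued throughout; `quantizeGray()` exists only
for export, because premature 8-bit rounding would shift the region
means that drive the snake.

A consequence worth noting: any tissue whose HU equals the level maps to
exactly mid-gray (127.5) *for every width*. Thrombus (~40 HU) sits at
the level, so what the width controls is where the *background* lands.
At $W=200$ fat (−80 HU) clamps to 0 and the outside mean drops far below
mid-gray, which is what places thrombus on the inside of the region-mean
midpoint. This is why the thrombus stage defaults to $W=200$ rather than
300: both are sensible "increased contrast" settings, but 300 leaves the
decision balanced on the noise for nominal AAA intensities.

## Preprocessing

Four slice-wise 2D filters are provided (median, Gaussian, bilateral,
fast patchwise non-local means), all with reflect padding so the image
border does not grow dark rims that would be detected as contours. The
pipeline default is the median filter with a 3-pixel window — the best
compromise between noise suppression and speed for CT slices. Filtering
is 2D because slice thickness varies across scanners, so a 3D kernel
would mix anisotropic information.

## Lumen segmentation by boundary propagation

Each slice is thresholded (default 200 on the 0–255 scale — robust for
contrasted arteries with few false positives) and the outer borders of
8-connected components become candidate contours. Holes are filled
before scoring, since the criteria describe solid vessel cross-sections.
Candidates are pruned by physical shape criteria:

* area of the filled region (mm²),
* aspect $A = \min(w,h)/\max(w,h)$ of the minimum-area rotated
  enclosing rectangle — near 1 for round vessels,
* solidity $S = a/ha$, area over convex-hull area — near 1 for smooth
  convex sections, low for spiky vertebral bone,
* contour perimeter (mm).

Two parameter sets are used. The *restrictive* set (area 175–2400 mm²,
$A \ge 0.75$, $S \ge 0.9$, perimeter ≤ 220 mm) localizes the aorta with
essentially no false positives: it brackets normal-to-aneurysmal aortic
diameters. The *permissive* set (4–2400 mm², $A \ge 0.2$, $S \ge 0.6$)
lets propagation follow small branch arteries. All six values are
config-exposed.

Surviving contours are chained across consecutive slices wherever their
filled regions share at least one pixel (the weakest reading of
"intersecting", exposed as `min_overlap`). The aorta is the longest
chain; ties go to the larger total area, then the more posterior
centroid (the aorta hugs the spine). From that seed the whole arterial
tree is grown breadth-first under the permissive criteria.

Two robustness mechanisms wrap this core:

* **Spine removal.** Vertebral bone saturates the same LUT as contrasted
  blood and can touch the aorta. The spine is segmented *first*, by the
  same stack mechanism at a bone threshold (230) with any-solidity
  criteria, selecting the longest stack whose mean solidity is below
  0.85 (vertebra cross-sections are spiky, vessels are smooth); the mask
  is closed slice-wise, dilated one voxel and blacked out of the working
  volume. When bone is actually fused to the lumen at these intensities
  the blackout is deliberately conservative: it sacrifices lumen
  coverage in the contact slices rather than leaking — the ACWE
  refinement stage is the remedy for the lost coverage.
* **Online error detection.** During propagation, a candidate whose area
  exceeds `jump_factor` (default 3×) times the area of the contour it
  grows from is rejected and counted; the count is reported in the run
  record. This is the minimal reading of online error correction: a
  sudden area jump means the contour has merged with another structure.

Chaining is a single deterministic greedy pass in slice order with fixed
tie-breaks (largest pixel overlap, then larger area); for
one-contour-per-slice vessel chains this equals any fixed-point
iteration, and end-to-end determinism is part of the test suite.

## Morphological ACWE

Active contours without edges minimize, over a closed surface
$\mathcal S$, an energy combining surface area (weight $\mu$), enclosed
volume (balloon weight $\nu$) and two data-attachment integrals
comparing the image $I$ with the mean intensity $c_1$ inside and $c_2$
outside $\mathcal S$ (weights $\lambda_1, \lambda_2$). The morphological
realization evolves a binary voxel region by:

1. **Balloon:** $|\nu|$ passes of binary dilation ($\nu>0$) or erosion
   ($\nu<0$) with the unit structuring element (the 3×3 in-plane
   footprint plus the two axial neighbours, so growth crosses slices).
2. **Data attachment:** boundary-band voxels (and every voxel the
   balloon just added) flip inside when
   $\lambda_1 |I - c_1| < \lambda_2 |I - c_2|$, flip outside on the
   reverse strict inequality, and *stay put on ties* — a constant image
   is a fixed point. The means are taken after the balloon, so a
   freshly inflated shell informs $c_1$; this is what lets a
   lumen-initialized snake calibrate the thrombus intensity
   automatically, with no user-picked sample region.
3. **Smoothing:** `n_smooth` (0–3) passes of the alternating operators
   $S_1 = E \circ D$ (even iterations) and $S_2 = D \circ E$ (odd),
   where $E$ is the sup of erosions and $D$ the inf of dilations over
   the four discrete line segments (horizontal, vertical, two
   diagonals) of length `pattern_size` ∈ {3, 5, 7}. Larger patterns
   prune wider protrusions: qualitatively weak / medium / strong
   smoothing.

Two deliberate deviations from the plainest reading deserve a note:

* **The balloon uses the unit element, not the smoothing pattern.** If
  the balloon advanced `pattern_size`-half-width voxels per iteration, a
  *stronger smoothing setting would also leak faster* through narrow
  contacts — inverting the observed ordering in which strong smoothing
  contains leakage. Scaling only the smoothing reproduces it.
* **Morphological proposals are gated by the data term.** A large
  closing pattern can add voxels far from the ±1 boundary band (for
  example, fat between the two iliac branches); those voxels would never
  be re-examined by a band-only attachment, the inside mean would drift
  toward background and the region would flood — we observed exactly
  this. Every voxel the balloon or the smoothing adds is therefore
  accepted only if it does not increase the data energy. Removals are
  never gated, so the smoothing retains full pruning power.

**Stopping.** Iterations stop when the relative volume change satisfies
$|\Delta V| / V < \text{tol}$ (default $10^{-6}$) or at `max_iter` (150
for lumen work; 25 suffices for thrombus at the increased contrast). A
numerical property worth knowing: $S_1$ and $S_2$ are not pairwise
idempotent on discrete shapes with single-pixel-wide extremes (the
rasterized disk of radius 10 has four such tips per slice), so the
alternation can settle into an exact period-2 cycle whose volume
oscillation never meets a tight tolerance — the region is correct, but
`converged` stays `FALSE` and the run ends at `max_iter`. Discrete disks
without 1-pixel tips (e.g. $r^2 = 90$) are exactly
smoothing-invariant, and the convergence benchmark uses one.

**Automatic initialization.** Candidate regions are the 6-connected
components of the thresholded volume; the one with maximal z-extent is
the aorta — the longest vertical bright structure in an abdominal CT.
No user interaction is needed.

## Thrombus segmentation

The segmented lumen is the initial level set. The CT is re-windowed at
$W=200$ (see above), lightly Gaussian-filtered ($\sigma=1$ px), and the
snake runs with inflation ($\nu=+1$), pattern 7×7 and a single smoothing
pass — the strong-single-smoothing setting; three medium (5×5) passes
behave similarly. Weak 3×3 smoothing lets the region escape through
narrow contacts into iso-intense neighbours (psoas muscle is ~45 HU
versus thrombus ~40 HU — indistinguishable by intensity alone); strong
smoothing prunes any intrusion narrower than its pattern. The returned
combined region is forced to contain the lumen (it is known foreground),
and the thrombus-only mask is the difference. The combined mask defines
the outer aortic wall used downstream.

## Calcification detection

Calcium absorbs far more than contrasted blood, so calcifications are
found by thresholding *raw HU* (the display LUT saturates both) above an
adaptive threshold: the mean HU over the segmented lumen times a factor
> 1 (default 1.5 — for contrast-enhanced lumen at 250–350 HU this lands
between lumen and typical calcium at > 500 HU). The search region is a
ring around the wall: slice-wise dilation minus erosion of the wall mask
with a disc of radius 3 voxels (≈ 2.4 mm — the scale of the aortic
wall). Using the combined lumen+thrombus wall instead of the lumen alone
moves the ring to the outer sac border and detects the calcifications
that sit there; the acceptance script reports the volume increase.

## Evaluation metrics

Voxel-overlap metrics (Dice, Jaccard, sensitivity, specificity),
volumetric similarity $VS = 1 - |FN - FP|/(2TP + FP + FN)$, and the
symmetric Hausdorff distance over voxel-center coordinates in mm. Two
conventions are ours: two empty regions compare as complete overlap
(DSC = JAC = 1, with a warning) so self-comparison is total, while the
Hausdorff distance of an empty mask is an error, keeping distance
semantics honest. The directed distances are evaluated against the
26-connectivity boundary of the other mask, which leaves the value
unchanged (the nearest mask voxel to an outside point is always a
boundary voxel) and keeps the computation tractable; the test suite
checks exact agreement with an exhaustive all-pairs oracle on random
masks. Per-slice cross-section surfaces (voxels × dx·dy) and their
Pearson correlation support slice-level method comparison; slices empty
in both series are excluded, and fewer than three paired slices give NA.

## The phantom: what it emulates, and what it does not

`generatePhantom()` builds, from a handful of analytic primitives, a CT
volume with the intensity ordering the pipeline assumes: a lumen tube
(300 HU) following a smooth curved centerline with a Gaussian aneurysmal
bulge (max lumen radius 14 mm), an iliac bifurcation and short renal
stubs; a thrombus annulus (40 HU) out to a 22 mm outer wall; a
full-height posterior spine column (700 HU) whose cross-section — a
vertebral body disc with posterior and transverse processes — is
deliberately spiky (solidity ≈ 0.75) so that shape, not intensity,
distinguishes it from the aorta; two paraspinal muscle columns (45 HU),
one in tangent contact with the aneurysm sac (~0.5 mm overlap, an
aperture of ~6 px — narrower than the strong smoothing pattern, wider
than the weak one, which is exactly the regime where smoothing strength
decides leakage); six calcification specks (900 HU, radius 1.3 mm),
three on the lumen wall away from the bulge and three on the outer sac
wall; additive Gaussian noise (σ = 15 HU) on a fat background (−80 HU).
Ground-truth masks are the exact pre-noise voxel sets, painted with
priority calcification > lumen > thrombus > spine > muscle > background
so they are pairwise disjoint. Presets re-create the qualitative
scenarios of the parameter studies: `touching_spine` (bone fused to the
sac over many slices), `low_contrast` (lumen tapering 300→150 HU toward
the feet — a poorly applied bolus; a uniformly ~150 HU lumen would make
detection fail outright everywhere rather than *stop early*, so the
taper is what exercises the graded failure), `stented_gap` (a 3-slice very bright band that
breaks the chain, the documented stent-graft failure mode), and
`ring_gap` (a 30° arc of the outer border erased from the image while
the truth keeps the intact ring, so border extrapolation can be
scored).

What the phantom does *not* emulate: organ backgrounds (kidneys, bowel
gas), beam-hardening or streak physics, partial-volume blur at tissue
interfaces, patient-to-patient anatomic variability, and real thrombus
texture. Passing the phantom suite therefore demonstrates the
*mechanics* of the pipeline — chaining, shape pruning, spine exclusion,
snake containment, adaptive thresholding, exact metrics — under
controlled contrast and noise; it does not certify clinical accuracy on
patient scans, for which expert-annotated data would be required.

## Problem sizes and determinism

The study phantom is 128³ voxels at 0.8 × 0.8 × 1.0 mm (a ~102 mm
field of view); ablation studies run on a 64³ grid at doubled spacing —
identical anatomy in mm, one eighth the voxels. The convergence
benchmark is a 64×64×48 noiseless cylinder. Everything downstream of
the phantom's seeded noise is deterministic: two runs with the same
configuration produce identical masks, which the suite asserts
end to end.

## Known limitations

* Vertebral bone fused to the lumen at bone-level thresholds cannot be
  separated by intensity; the conservative blackout trades lumen
  coverage in contact slices for zero leakage.
* Structures within ~2 HU of thrombus (muscle) are indistinguishable by
  the data term; containment relies entirely on smoothing geometry.
* Metallic stent artifacts break the propagation chain (detection stops
  at the band); no recovery is attempted beyond reporting.
* The smoothing alternation's period-2 cycles mean `converged = FALSE`
  is common on real, rough shapes even when the segmentation is good;
  treat `max_iter` as the practical stopping rule there.
* Surface export is an exact voxel-face triangulation: watertight and
  area-exact for the voxel set, but axis-aligned (a smooth sphere's
  voxel surface area exceeds $4\pi r^2$ by a known ~1.5 factor); no
  iso-surface interpolation is performed.
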