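Package: aortaseg
Title: Automated Segmentation of Abdominal Aortic Aneurysms in Contrast CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automated segmentation pipeline for abdominal aortic
    aneurysms (AAA) in arterial-phase contrast CT volumes. Implements
    Hounsfield-unit windowing, slice-wise denoising, aortic lumen detection
    by vertical boundary-contour propagation with prior spine removal,
    morphological active contours without edges (ACWE) for lumen refinement
    and intraluminal thrombus growth, ring-masked adaptive-threshold
    calcification detection, and a full segmentation-evaluation metric
    suite (Dice, Jaccard, sensitivity, specificity, volume similarity,
    Hausdorff distance). Ships a deterministic synthetic CT phantom
    generator with ground-truth masks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    RNifti,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
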