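# Four-stage pipeline orchestration: preprocessing, lumen segmentation
# (spine removal + boundary propagation, optional ACWE refinement),
# thrombus growth, calcification detection; plus static exports (NIfTI
# masks, STL surface meshes, PNG slice renderings) and a run record.

#' Pipeline configuration
#'
#' Nested list of all stage parameters with full defaults; any subset can
#' be overridden. Stage toggles: \code{preprocess}, \code{spine},
#' \code{acwe_refine}, \code{thrombus}, \code{calcification}.
#'
#' @param window lumen [windowSettings()].
#' @param filter a [filterSpec()] for preprocessing.
#' @param propagation a [propagationParams()].
#' @param snake a [snakeParams()] for optional ACWE lumen refinement.
#' @param thrombus a [thrombusParams()].
#' @param calcification a [calcParams()].
#' @param stages named logical overrides of the stage toggles.
#' @param output_dir if non-NULL, masks and the run record are written
#'   there.
#' @return A \code{PipelineConfig} object.
#' @export
pipelineConfig <- function(window = windowSettings(),
                           filter = filterSpec(),
                           propagation = propagationParams(),
                           snake = snakeParams(),
                           thrombus = thrombusParams(),
                           calcification = calcParams(),
                           stages = list(),
                           output_dir = NULL) {
  st <- utils::modifyList(
    list(preprocess = TRUE, spine = TRUE, acwe_refine = FALSE,
         thrombus = TRUE, calcification = TRUE), stages)
  cfg <- structure(list(window = window, filter = filter,
                        propagation = propagation, snake = snake,
                        thrombus = thrombus,
                        calcification = calcification,
                        stages = st, output_dir = output_dir),
                   class = "PipelineConfig")
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks cross-stage consistency before any computation: calcification
#' with \code{wall_source = "thrombus"} requires the thrombus stage.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly TRUE; errors on inconsistency.
#' @export
validatePipelineConfig <- function(config) {
  if (!inherits(config, "PipelineConfig"))
    stop("config must be a PipelineConfig", call. = FALSE)
  if (config$stages$calcification && !config$stages$thrombus &&
      config$calcification$wall_source == "thrombus")
    stop(paste("configuration error: calcification wall_source is",
               "'thrombus' but the thrombus stage is disabled"),
         call. = FALSE)
  invisible(TRUE)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipelineConfig()] arguments
#' (\code{window.level}, \code{filter.method}, \code{propagation.threshold},
#' \code{snake.nu}, \code{thrombus.pattern_size},
#' \code{calcification.factor}, \code{stages.*}, ...); anything omitted
#' keeps its default.
#'
#' @param path YAML file.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$window)) args$window <- do.call(windowSettings, y$window)
  if (!is.null(y$filter)) args$filter <- do.call(filterSpec, y$filter)
  if (!is.null(y$propagation)) {
    pr <- y$propagation
    for (f in c("restrictive", "permissive"))
      if (!is.null(pr[[f]]))
        pr[[f]] <- do.call(shapeCriteria, c(list(preset = f), pr[[f]]))
    args$propagation <- do.call(propagationParams, pr)
  }
  if (!is.null(y$snake)) args$snake <- do.call(snakeParams, y$snake)
  if (!is.null(y$thrombus)) {
    th <- y$thrombus
    if (!is.null(th$window)) th$window <- do.call(windowSettings, th$window)
    args$thrombus <- do.call(thrombusParams, th)
  }
  if (!is.null(y$calcification))
    args$calcification <- do.call(calcParams, y$calcification)
  if (!is.null(y$stages)) args$stages <- y$stages
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  do.call(pipelineConfig, args)
}

.loadInput <- function(input) {
  if (is(input, "CTVolume")) return(input)
  if (is.character(input) && dir.exists(input))
    return(readDicomSeries(input))
  if (is.character(input) && file.exists(input))
    return(readVolume(input))
  stop("input must be a CTVolume, a DICOM directory or a volume file",
       call. = FALSE)
}

#' Run the full segmentation pipeline
#'
#' Stages in order: windowing + denoising, spine segmentation, aorta
#' localization and arterial propagation (optionally refined by an ACWE
#' snake), thrombus growth, calcification detection. A stage failure
#' aborts with the stage name; the partial results gathered so far are
#' attached to the error condition as \code{partial}.
#'
#' @param input a [CTVolume-class], a DICOM directory or a NIfTI file.
#' @param config a [pipelineConfig()].
#' @return A list: \code{masks} (lumen, spine, thrombus, wall,
#'   calcification — absent stages give NULL), \code{gray} (the working
#'   [GrayVolume-class]), \code{record} (per-stage timings, iteration
#'   counts, warnings and the parameter snapshot).
#' @export
runPipeline <- function(input, config = pipelineConfig()) {
  validatePipelineConfig(config)
  masks <- list(lumen = NULL, spine = NULL, thrombus = NULL, wall = NULL,
                calcification = NULL)
  record <- list(stages = list(), warnings = character(),
                 config = .configSnapshot(config))
  runStage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      cond <- simpleError(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      class(cond) <- c("pipelineStageError", class(cond))
      cond$stage <- name
      cond$partial <- list(masks = masks, record = record)
      stop(cond)
    })
    record$stages[[name]] <<-
      list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  ct <- runStage("load", function() .loadInput(input))
  gray <- runStage("preprocess", function() {
    g <- applyWindow(ct, config$window)
    if (config$stages$preprocess) g <- denoiseVolume(g, config$filter)
    g
  })
  if (config$stages$spine) {
    masks$spine <- runStage("spine", function()
      segmentSpine(gray, config$propagation))
    record$stages$spine$voxels <- sum(voxels(masks$spine))
  }
  lum <- runStage("lumen", function()
    segmentLumen(gray, config$propagation, spine = masks$spine))
  masks$lumen <- lum$lumen
  record$stages$lumen$rejected_area_jumps <-
    attr(lum$lumen, "rejected")
  if (!is.null(attr(lum$lumen, "rejected")) &&
      attr(lum$lumen, "rejected") > 0)
    record$warnings <- c(record$warnings,
      sprintf("online error detection rejected %d candidate contour(s)",
              attr(lum$lumen, "rejected")))
  if (config$stages$acwe_refine) {
    ref <- runStage("acwe_refine", function()
      acweEvolve(gray, masks$lumen, config$snake))
    masks$lumen <- ref$mask
    record$stages$acwe_refine$iterations <- ref$iterations
    if (!ref$converged)
      record$warnings <- c(record$warnings,
        "ACWE refinement hit max_iter without meeting the tolerance")
  }
  if (config$stages$thrombus) {
    th <- runStage("thrombus", function()
      segmentThrombus(ct, masks$lumen, config$thrombus))
    masks$thrombus <- th$thrombus
    masks$wall <- th$combined
    record$stages$thrombus$iterations <- th$iterations
    if (!th$converged)
      record$warnings <- c(record$warnings,
        "thrombus snake hit max_iter without meeting the tolerance")
  }
  if (config$stages$calcification) {
    masks$calcification <- runStage("calcification", function() {
      wall <- if (config$calcification$wall_source == "thrombus")
        masks$wall else masks$lumen
      segmentCalcifications(ct, wall, masks$lumen, config$calcification,
                            exclude = masks$spine)
    })
    record$stages$calcification$threshold_hu <-
      attr(masks$calcification, "threshold")
    record$stages$calcification$volume_mm3 <-
      calcVolume(masks$calcification)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(masks))
      if (!is.null(masks[[nm]]))
        writeMask(masks[[nm]],
                  file.path(config$output_dir, paste0(nm, ".nii.gz")))
    yaml::write_yaml(record, file.path(config$output_dir, "run_record.yaml"))
  }
  list(masks = masks, gray = gray, record = record)
}

.configSnapshot <- function(config) {
  rapply(unclass(config), function(x) x, how = "list")
}

#' Export a mask surface as an STL mesh
#'
#' Exact voxel-face triangulation: every boundary face between a set and
#' an unset (or out-of-grid) voxel contributes two triangles with outward
#' normals, in physical mm coordinates. The mesh is closed and watertight
#' by construction; a single-voxel mask yields the 12 triangles of its
#' cube.
#'
#' @param mask a non-empty [BinaryMask3D-class].
#' @param path output STL file (ASCII).
#' @return Invisibly, the number of triangles written.
#' @export
exportMesh <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask3D"))
  arr <- voxels(mask)
  if (!sum(arr)) stop("cannot mesh an empty mask", call. = FALSE)
  sp <- spacing(mask)
  dims <- dim(arr)
  tris <- list()
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  idx <- which(arr == 1L)
  co <- arrayInd(idx, dims)
  for (d in dirs) {
    nb <- sweep(co, 2, d, "+")
    inGrid <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
              nb[, 2] >= 1 & nb[, 2] <= dims[2] &
              nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nbSet <- logical(nrow(co))
    nbSet[inGrid] <- arr[nb[inGrid, , drop = FALSE]] == 1L
    face <- co[!nbSet, , drop = FALSE]
    if (!nrow(face)) next
    tris[[length(tris) + 1L]] <- list(tri = .faceTriangles(face, d, sp),
                                      normal = d)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mask", con)
  ntri <- 0L
  for (part in tris) {
    tri <- part$tri
    nrm <- part$normal
    for (i in seq_len(nrow(tri) / 3)) {
      v <- tri[(3 * i - 2):(3 * i), , drop = FALSE]
      writeLines(c(
        sprintf("facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
        "  outer loop",
        sprintf("    vertex %g %g %g", v[, 1], v[, 2], v[, 3]),
        "  endloop", "endfacet"), con)
      ntri <- ntri + 1L
    }
  }
  writeLines("endsolid mask", con)
  invisible(ntri)
}

# two CCW triangles per exposed voxel face, outward normal along d
.faceTriangles <- function(face, d, sp) {
  ax <- which(d != 0)
  others <- setdiff(1:3, ax)
  ctr <- sweep(face, 2, sp, "*")
  ctr[, ax] <- ctr[, ax] + d[ax] * sp[ax] / 2
  u <- c(0, 0, 0); v <- c(0, 0, 0)
  u[others[1]] <- sp[others[1]] / 2
  v[others[2]] <- sp[others[2]] / 2
  # orient (u, v, normal) right-handed
  if (sum((.cross3(u, v)) * d) < 0) { tmp <- u; u <- v; v <- tmp }
  c1 <- sweep(sweep(ctr, 2, u, "-"), 2, v, "-")
  c2 <- sweep(sweep(ctr, 2, u, "+"), 2, v, "-")
  c3 <- sweep(sweep(ctr, 2, u, "+"), 2, v, "+")
  c4 <- sweep(sweep(ctr, 2, u, "-"), 2, v, "+")
  tri <- matrix(0, 6 * nrow(face), 3)
  tri[seq(1, nrow(tri), 6), ] <- c1
  tri[seq(2, nrow(tri), 6), ] <- c2
  tri[seq(3, nrow(tri), 6), ] <- c3
  tri[seq(4, nrow(tri), 6), ] <- c1
  tri[seq(5, nrow(tri), 6), ] <- c3
  tri[seq(6, nrow(tri), 6), ] <- c4
  tri
}

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Render one axial slice with mask contour overlays as PNG
#'
#' @param gray a [GrayVolume-class].
#' @param z slice index.
#' @param overlays named list of [BinaryMask3D-class] masks; names pick
#'   the overlay colour (lumen red, thrombus green, spine blue,
#'   calcification yellow, anything else magenta). Only the mask boundary
#'   pixels are coloured.
#' @param path output PNG file.
#' @return Invisibly, the path.
#' @export
renderSlice <- function(gray, z, overlays = list(), path) {
  stopifnot(is(gray, "GrayVolume"))
  v <- voxels(gray)
  if (z < 1 || z > dim(v)[3])
    stop("slice index out of range", call. = FALSE)
  sl <- v[, , z] / 255
  img <- array(rep(sl, 3), c(dim(sl), 3))
  cols <- list(lumen = c(1, 0, 0), thrombus = c(0, 1, 0),
               spine = c(0.2, 0.4, 1), calcification = c(1, 1, 0))
  for (nm in names(overlays)) {
    m <- .asMaskArray(overlays[[nm]])[, , z]
    if (!sum(m)) next
    arr3 <- array(m, c(dim(m), 1L))
    er <- .morphArr(arr3, .starOffsets2D(3L), FALSE)[, , 1]
    b <- m == 1L & er == 0L
    colr <- if (!is.null(cols[[nm]])) cols[[nm]] else c(1, 0, 1)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[b] <- colr[ch]
      img[, , ch] <- pl
    }
  }
  # PNG rows are the image's y axis
  png::writePNG(aperm(img, c(2, 1, 3)), path)
  invisible(path)
}
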