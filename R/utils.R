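# Internal helpers shared across modules: structuring-element families,
# binary morphology on raw 3D arrays (via compiled kernels), connected
# components and coordinate extraction. Masks travel internally as integer
# 0/1 arrays; S4 wrapping happens at module surfaces.

# the four discrete line segments (horizontal, vertical, two diagonals) of
# length k through the origin, in-plane (z offset 0)
.linePatterns <- function(k) {
  stopifnot(k %in% c(3L, 5L, 7L))
  h <- (k - 1L) %/% 2L
  d <- -h:h
  lapply(list(cbind(d, 0L), cbind(0L, d), cbind(d, d), cbind(d, -d)),
         function(m) cbind(m, 0L))
}

# union footprint of the line family: for k = 3 the full 3x3 square,
# for k = 5/7 a star in-plane
.starOffsets2D <- function(k) {
  unique(do.call(rbind, .linePatterns(k)))
}

# quasi-3D footprint: in-plane star plus the two axial neighbours, so the
# balloon force can grow through slices
.starOffsets3D <- function(k) {
  rbind(.starOffsets2D(k), c(0L, 0L, 1L), c(0L, 0L, -1L))
}

.box26 <- function() {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  storage.mode(g) <- "integer"
  g
}

.asMaskArray <- function(m) {
  if (is(m, "BinaryMask3D")) m <- voxels(m)
  d <- dim(m)
  m <- as.integer(m != 0)
  dim(m) <- d
  m
}

.morphArr <- function(arr, offsets, dilate) {
  storage.mode(offsets) <- "integer"
  cpp_morph(arr, dim(arr), offsets, dilate)
}

# sup of erosions over the line family (curvature-like smoothing primitive)
.supErosion <- function(arr, k) {
  cpp_line_morph(arr, dim(arr), as.integer(k), 0L)
}

# inf of dilations over the line family
.infDilation <- function(arr, k) {
  cpp_line_morph(arr, dim(arr), as.integer(k), 1L)
}

.label3dArr <- function(arr, connectivity = 6L) {
  cpp_label3d(arr, dim(arr), as.integer(connectivity))
}

# 26-connectivity boundary voxels of a mask (voxels of the mask with at
# least one background neighbour or on the grid edge)
.boundaryArr <- function(arr) {
  er <- .morphArr(arr, .box26(), FALSE)
  out <- arr
  out[er == 1L] <- 0L
  out
}

# physical coordinates (mm) of set voxels, n x 3 matrix
.maskCoordsMM <- function(arr, spacing) {
  idx <- which(arr != 0L)
  if (!length(idx)) return(matrix(numeric(0), 0, 3))
  co <- arrayInd(idx, dim(arr))
  cbind(co[, 1] * spacing[1], co[, 2] * spacing[2], co[, 3] * spacing[3])
}

# reflect-pad a 2D matrix by `h` pixels on every side
.padReflect <- function(m, h) {
  nx <- nrow(m); ny <- ncol(m)
  ix <- c(rev(seq_len(h) + 1L), seq_len(nx), nx - seq_len(h))
  iy <- c(rev(seq_len(h) + 1L), seq_len(ny), ny - seq_len(h))
  m[ix, iy, drop = FALSE]
}

.restoreSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  restore <- .restoreSeed()
  on.exit(restore())
  set.seed(seed)
  expr
}
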