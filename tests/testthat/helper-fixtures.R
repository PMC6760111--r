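# Shared fixtures, generated in code and memoized across test files.
# Heavy artifacts (the 128^3 phantom and its pipeline run) are built once
# per test session.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# two-intensity cylinder whose discrete cross-section (r^2 = 90) has no
# single-pixel protrusions, so it is exactly invariant under the
# morphological smoothing operators
cylinderFixture <- function(nx = 64, ny = 64, nz = 48, r2 = 90,
                            inside = 200, outside = 50) {
  X <- matrix(seq_len(nx), nx, ny)
  Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  disk <- (X - nx / 2)^2 + (Y - ny / 2)^2 <= r2
  v <- array(outside, c(nx, ny, nz))
  truth <- array(0L, c(nx, ny, nz))
  for (z in seq_len(nz)) {
    sl <- v[, , z]; sl[disk] <- inside; v[, , z] <- sl
    truth[, , z] <- disk
  }
  list(gray = GrayVolume(v), truth = BinaryMask3D(truth), disk = disk)
}

# seed disk mask on one slice, centred, radius^2 r2
seedSliceMask <- function(dims, z, r2 = 16) {
  X <- matrix(seq_len(dims[1]), dims[1], dims[2])
  Y <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  m <- array(0L, dims)
  m[, , z] <- (X - dims[1] / 2)^2 + (Y - dims[2] / 2)^2 <= r2
  BinaryMask3D(m)
}

# the full-size study phantom and its segmentation pipeline run
idealPhantom <- function() {
  memoFixture("ideal_phantom", function() generatePhantom(phantomPreset("ideal")))
}

idealPipeline <- function() {
  memoFixture("ideal_pipeline", function()
    runPipeline(idealPhantom()$ct, pipelineConfig()))
}

# coarse-grid variant of a preset: identical anatomy in mm on an 8x
# smaller voxel grid, for the cheaper ablation studies
coarsePreset <- function(name, ...) {
  phantomPreset(name, shape = c(64L, 64L, 64L), spacing = c(1.6, 1.6, 2.0),
                ...)
}

# small ring phantom (lumen + thrombus annulus only) for thrombus tests
ringFixture <- function() {
  memoFixture("ring_phantom", function()
    generatePhantom(phantomSpec(shape = c(64L, 64L, 64L),
                                spacing = c(1.6, 1.6, 2.0),
                                renal = FALSE, spine = FALSE,
                                calc_wall_count = 0L, calc_outer_count = 0L)))
}

# brute-force metric oracles (independent of the implementation path)
bruteConfusion <- function(a, b) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) tp <- tp + 1L
    else if (a[i] == 0 && b[i] == 1) fp <- fp + 1L
    else if (a[i] == 1 && b[i] == 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

bruteHausdorff <- function(a, b, sp) {
  ca <- which(a == 1, arr.ind = TRUE)
  cb <- which(b == 1, arr.ind = TRUE)
  dm <- matrix(0, nrow(ca), nrow(cb))
  for (i in seq_len(nrow(ca)))
    for (j in seq_len(nrow(cb)))
      dm[i, j] <- sqrt(sum(((ca[i, ] - cb[j, ]) * sp)^2))
  max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
}

randomMaskPair <- function(dims = c(8, 8, 8), p = 0.3, spacing = c(1, 1, 1)) {
  a <- array(stats::rbinom(prod(dims), 1, p), dims)
  b <- array(stats::rbinom(prod(dims), 1, p), dims)
  list(a = BinaryMask3D(a, spacing), b = BinaryMask3D(b, spacing),
       arrA = a, arrB = b)
}

# independent 8-connectivity component count (plain R flood fill)
brute8Components <- function(b) {
  lab <- matrix(0L, nrow(b), ncol(b))
  nxt <- 0L
  for (s in which(b != 0)) {
    if (lab[s]) next
    nxt <- nxt + 1L
    stack <- s
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[cur]) next
      lab[cur] <- nxt
      ci <- (cur - 1L) %% nrow(b) + 1L
      cj <- (cur - 1L) %/% nrow(b) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- ci + di; jj <- cj + dj
        if (ii >= 1 && ii <= nrow(b) && jj >= 1 && jj <= ncol(b) &&
            b[ii, jj] != 0 && lab[ii, jj] == 0L)
          stack <- c(stack, (jj - 1L) * nrow(b) + ii)
      }
    }
  }
  nxt
}
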