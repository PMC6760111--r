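rasterDiskArr <- function(n, nz, cx, cy, r2) {
  X <- matrix(seq_len(n), n, n)
  Y <- matrix(seq_len(n), n, n, byrow = TRUE)
  disk <- (X - cx)^2 + (Y - cy)^2 <= r2
  array(rep(disk + 0L, nz), c(n, n, nz))
}

test_that("ring mask is an annulus disjoint from the eroded interior", {
  wall <- BinaryMask3D(rasterDiskArr(40, 2, 20, 20, 100))
  ring <- ringMask(wall, 2L)
  # the disc structuring element reaches at most ~2.9 px for radius 2
  inner <- rasterDiskArr(40, 2, 20, 20, 49)
  expect_identical(sum(voxels(ring) & inner), 0L)
  outer <- rasterDiskArr(40, 2, 20, 20, 170)
  expect_true(all(voxels(ring) <= outer))
  expect_gt(sum(voxels(ring)), 0)
  # by construction the ring excludes the eroded wall
  brush <- EBImage::makeBrush(5, "disc")
  er <- voxels(wall)
  for (z in 1:2) er[, , z] <- as.integer(EBImage::erode(er[, , z], brush))
  expect_identical(sum(voxels(ring) & er), 0L)
  # empty wall -> empty ring
  expect_identical(sum(voxels(ringMask(BinaryMask3D(array(0L, c(8, 8, 2))),
                                       2L))), 0L)
  # single-voxel wall: erosion empty, ring = its disc neighbourhood
  one <- array(0L, c(11, 11, 1)); one[6, 6, 1] <- 1L
  r1 <- voxels(ringMask(BinaryMask3D(one), 1L))
  expect_gte(sum(r1), 4)
  expect_identical(r1[6, 6, 1], 1L)
})

test_that("adaptive threshold is factor x mean lumen HU", {
  ct <- CTVolume(array(300, c(6, 6, 2)))
  lum <- BinaryMask3D(array(1L, c(6, 6, 2)))
  expect_equal(calcThreshold(ct, lum, 1.5), 450)
  expect_error(calcThreshold(ct, lum, 1.0), "superior to one")
  expect_error(calcParams(factor = 0.9), "superior to one")
  set.seed(40)
  v <- array(round(stats::rnorm(6^3, 300, 40)), c(6, 6, 6))
  m <- array(stats::rbinom(6^3, 1, 0.5), c(6, 6, 6))
  expect_equal(calcThreshold(CTVolume(v), BinaryMask3D(m), 1.2),
               1.2 * sum(v[m == 1]) / sum(m), tolerance = 1e-14)
  expect_error(calcThreshold(ct, BinaryMask3D(array(0L, c(6, 6, 2))), 1.5),
               "empty")
})

test_that("calcifications are detected in the ring, nowhere else, monotone in factor", {
  # lumen disk 300 HU with two 900 HU specks on its wall, fat background
  n <- 48; nz <- 6
  v <- array(-80, c(n, n, nz))
  lum <- rasterDiskArr(n, nz, 24, 24, 100)
  v[lum == 1L] <- 300
  specks <- array(0L, c(n, n, nz))
  specks[34, 24, 3] <- 1L; specks[24, 14, 4] <- 1L   # on the r=10 wall
  v[specks == 1L] <- 900
  ct <- CTVolume(v)
  lumen <- BinaryMask3D(lum * (1L - specks))
  res <- segmentCalcifications(ct, lumen, lumen, calcParams(ring_radius = 3,
                                                            factor = 1.5))
  expect_identical(sum(voxels(res) & specks), sum(specks))
  expect_identical(sum(voxels(res)), sum(specks))    # nothing else
  expect_equal(attr(res, "threshold"), 450, tolerance = 1)
  # no specks -> empty mask
  v2 <- v; v2[specks == 1L] <- 300
  res2 <- segmentCalcifications(CTVolume(v2), lumen, lumen, calcParams())
  expect_identical(sum(voxels(res2)), 0L)
  # detected volume monotone non-increasing in factor
  vols <- vapply(c(1.2, 1.5, 2.5, 3.5), function(f)
    calcVolume(segmentCalcifications(ct, lumen, lumen,
                                     calcParams(factor = f))), numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("calcification mask is confined to the ring and excluded from the core", {
  ph <- ringFixture()
  wall <- BinaryMask3D(voxels(ph$truth$lumen) | voxels(ph$truth$thrombus),
                       spacing(ph$ct), "wall")
  p <- calcParams(ring_radius = 2)
  calc <- segmentCalcifications(ph$ct, wall, ph$truth$lumen, p)
  ring <- voxels(ringMask(wall, 2L))
  expect_true(all(voxels(calc) <= ring))
  core <- voxels(erodeMask(wall, 5))
  expect_identical(sum(voxels(calc) & core), 0L)
})

test_that("mask volume is voxel count times voxel volume", {
  expect_equal(calcVolume(BinaryMask3D(array(0L, c(4, 4, 4)))), 0)
  m <- array(0L, c(4, 4, 4)); m[1:10] <- 1L
  expect_equal(calcVolume(BinaryMask3D(m, spacing = c(1, 1, 1))), 10)
  m8 <- array(0L, c(4, 4, 4)); m8[1:8] <- 1L
  expect_equal(calcVolume(BinaryMask3D(m8, spacing = c(0.5, 0.5, 1))), 2)
})
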