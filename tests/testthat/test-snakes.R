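test_that("erode/dilate behave on canonical masks", {
  ones <- BinaryMask3D(array(1L, c(8, 8, 3)))
  expect_identical(voxels(dilateMask(ones)), voxels(ones))
  one <- array(0L, c(9, 9, 3)); one[5, 5, 2] <- 1L
  d <- voxels(dilateMask(BinaryMask3D(one), 3L))
  expect_identical(sum(d), 9L)              # full 3x3 in-plane footprint
  expect_identical(sum(d[, , 2]), 9L)
  d3 <- voxels(dilateMask(BinaryMask3D(one), 3L, axial = TRUE))
  expect_identical(sum(d3), 11L)            # plus the two axial neighbours
  # erosion of a single voxel is empty
  expect_identical(sum(voxels(erodeMask(BinaryMask3D(one)))), 0L)
})

test_that("erode(dilate(disk)) recovers the disk within a 1-pixel band", {
  X <- matrix(1:40, 40, 40); Y <- matrix(1:40, 40, 40, byrow = TRUE)
  disk <- array(((X - 20)^2 + (Y - 20)^2 <= 100) + 0L, c(40, 40, 1))
  m <- BinaryMask3D(disk)
  back <- voxels(erodeMask(dilateMask(m)))
  grown <- voxels(dilateMask(m)); shrunk <- voxels(erodeMask(m))
  expect_true(all(back >= shrunk))
  expect_true(all(back <= grown))
  expect_true(all(back[disk == 1L & shrunk == 1L] == 1L))
})

test_that("smoothing: identity at n=0, solid rectangles invariant, speckle reduced", {
  set.seed(30)
  r <- array(0L, c(20, 20, 2)); r[5:15, 4:16, ] <- 1L
  m <- BinaryMask3D(r)
  expect_identical(voxels(smoothMask(m, 3, 0L)), r)
  # invariance up to the pattern-scale boundary band: the interior beyond
  # (k-1)/2 + 1 pixels is preserved and nothing grows outside the solid
  for (parity in 0:1)
    for (k in c(3, 5, 7)) {
      h <- (k - 1) / 2 + 1
      inner <- array(0L, dim(r))
      inner[(5 + h):(15 - h), (4 + h):(16 - h), ] <- 1L
      sm <- voxels(smoothMask(m, k, 1L, parity))
      expect_true(all(sm[inner == 1L] == 1L), info = paste(k, parity))
      expect_true(all(sm <= r), info = paste(k, parity))
    }
  # speckled disk: boundary transitions strictly reduced
  X <- matrix(1:40, 40, 40); Y <- matrix(1:40, 40, 40, byrow = TRUE)
  disk <- ((X - 20)^2 + (Y - 20)^2 <= 120) + 0L
  noise <- matrix(stats::rbinom(1600, 1, 0.08), 40, 40)
  sp <- array((disk + noise) %% 2L, c(40, 40, 1))
  transitions <- function(a) {
    sum(abs(diff(a[, , 1]))) + sum(abs(t(diff(t(a[, , 1])))))
  }
  sm <- voxels(smoothMask(BinaryMask3D(sp), 3, 3L))
  expect_lt(transitions(sm), transitions(sp))
})

test_that("region means match direct summation and warn on empty regions", {
  set.seed(31)
  img <- array(stats::runif(6^3, 0, 255), c(6, 6, 6))
  mask <- array(stats::rbinom(6^3, 1, 0.4), c(6, 6, 6))
  cm <- regionMeans(GrayVolume(img), BinaryMask3D(mask))
  expect_equal(unname(cm["c1"]), sum(img[mask == 1]) / sum(mask),
               tolerance = 1e-14)
  expect_equal(unname(cm["c2"]), sum(img[mask == 0]) / sum(mask == 0),
               tolerance = 1e-14)
  const <- GrayVolume(array(100, c(4, 4, 4)))
  half <- array(0L, c(4, 4, 4)); half[1:2, , ] <- 1L
  expect_equal(unname(regionMeans(const, BinaryMask3D(half))), c(100, 100))
  expect_warning(regionMeans(const, BinaryMask3D(array(0L, c(4, 4, 4)))),
                 "empty")
})

test_that("a constant image with equal weights is a fixed point of the data step", {
  const <- GrayVolume(array(100, c(12, 12, 6)))
  init <- seedSliceMask(c(12, 12, 6), 3, r2 = 9)
  st <- acweStep(const, init, snakeParams(nu = 0, n_smooth = 0), 0L)
  expect_identical(voxels(st$mask), voxels(init))
  expect_equal(st$dV, 0)
})

test_that("the snake grows monotonically toward a bright disk early on", {
  cyl <- cylinderFixture()
  init <- seedSliceMask(dim(voxels(cyl$gray)), 24)
  m <- init
  p <- snakeParams(nu = 1, n_smooth = 1)
  prev <- sum(voxels(m))
  for (i in 0:4) {
    st <- acweStep(cyl$gray, m, p, i)
    m <- st$mask
    expect_gt(st$volume, prev)
    prev <- st$volume
    expect_true(all(voxels(m)[cyl$disk == FALSE]) == 0)
  }
})

test_that("ACWE converges on the cylinder and truth init is a fixed point", {
  cyl <- cylinderFixture()
  res <- acweEvolve(cyl$gray, seedSliceMask(dim(voxels(cyl$gray)), 24),
                    snakeParams(nu = 1, n_smooth = 1, max_iter = 150))
  expect_true(res$converged)
  expect_lte(res$iterations, 50)
  expect_gte(diceCoefficient(cyl$truth, res$mask), 0.98)

  fp <- acweEvolve(cyl$gray, cyl$truth, snakeParams(nu = 0, n_smooth = 1))
  expect_lte(fp$iterations, 2)
  expect_identical(voxels(fp$mask), voxels(cyl$truth))

  one <- acweEvolve(cyl$gray, cyl$truth,
                    snakeParams(nu = 1, n_smooth = 0, max_iter = 1))
  expect_identical(one$iterations, 1L)
})

test_that("result is invariant to seed placement inside the target", {
  cyl <- cylinderFixture(nz = 24)
  p <- snakeParams(nu = 1, n_smooth = 1, max_iter = 100)
  r1 <- acweEvolve(cyl$gray, seedSliceMask(dim(voxels(cyl$gray)), 6), p)
  r2 <- acweEvolve(cyl$gray, seedSliceMask(dim(voxels(cyl$gray)), 20), p)
  expect_identical(voxels(r1$mask), voxels(r2$mask))
})

test_that("intensity swap with complemented init yields the complemented region", {
  cyl <- cylinderFixture(nz = 8)
  swapped <- GrayVolume(250 - voxels(cyl$gray))
  p <- snakeParams(nu = 0, n_smooth = 0, max_iter = 20)
  a <- acweEvolve(cyl$gray, cyl$truth, p)
  comp <- BinaryMask3D(1L - voxels(cyl$truth))
  b <- acweEvolve(swapped, comp, p)
  expect_identical(voxels(b$mask), 1L - voxels(a$mask))
})

test_that("a deflating snake on a dark image collapses with an error", {
  dark <- GrayVolume(array(0, c(10, 10, 4)))
  init <- seedSliceMask(c(10, 10, 4), 2, r2 = 4)
  expect_error(acweEvolve(dark, init,
                          snakeParams(nu = -1, n_smooth = 0, max_iter = 50)),
               "collapsed")
  expect_error(acweEvolve(dark, BinaryMask3D(array(0L, c(10, 10, 4)))),
               "empty")
})

test_that("automatic initialization picks the component with maximal z-extent", {
  v <- array(0, c(20, 20, 30))
  v[10, 10, 3:25] <- 255       # tall thin column: z-extent 23
  v[4:8, 4:8, 5:9] <- 255      # bright blob: z-extent 5
  g <- GrayVolume(v)
  init <- autoInitLumen(g, 200)
  expect_true(all(which(voxels(init) == 1L) %in% which(v == 255)))
  expect_identical(sum(voxels(init)), 23L)
  one <- array(0, c(5, 5, 5)); one[2, 3, 4] <- 255
  expect_identical(sum(voxels(autoInitLumen(GrayVolume(one), 200))), 1L)
  expect_error(autoInitLumen(GrayVolume(array(0, c(5, 5, 5))), 200),
               "no initial region")
})

test_that("weight-ratio sweep: reference cell is exact and DSC <= 1 elsewhere", {
  cyl <- cylinderFixture(nz = 16)
  blur <- denoiseVolume(cyl$gray, filterSpec("gaussian", sigma = 1))
  tab <- wrSmoothingSweep(blur, cyl$truth, wr = c(1, 2), n_smooth = c(0, 1),
                          params = snakeParams(nu = 0, max_iter = 30))
  expect_equal(tab$dsc[tab$wr == 1 & tab$n_smooth == 0], 1)
  expect_true(all(tab$dsc >= 0 & tab$dsc <= 1))
})
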