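rasterDisk <- function(n, cx, cy, r2, value = 1) {
  X <- matrix(seq_len(n), n, n)
  Y <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((X - cx)^2 + (Y - cy)^2 <= r2) * value
}

test_that("binarization thresholds at G >= t", {
  sl <- matrix(c(0, 100, 199.9, 200, 255), 5, 1)
  expect_identical(sum(binarizeSlice(sl, 0)), 5L)
  expect_identical(sum(binarizeSlice(sl, 200)), 2L)
  expect_identical(sum(binarizeSlice(sl, 255.0)), 1L)
  expect_error(binarizeSlice(sl, 300), "threshold")
  disk <- rasterDisk(40, 20, 20, 100, 200) + 50 * (rasterDisk(40, 20, 20, 100) == 0)
  expect_identical(sum(binarizeSlice(disk, 200)), sum(rasterDisk(40, 20, 20, 100) != 0))
})

test_that("one contour per 8-connected component, filled region exact", {
  expect_identical(findContours(matrix(0, 10, 10)), list())
  two <- matrix(0, 20, 20); two[2:5, 2:5] <- 1; two[10:14, 10:14] <- 1
  expect_length(findContours(two), 2L)
  disk <- rasterDisk(40, 20, 20, 100)
  cs <- findContours(disk)
  expect_length(cs, 1L)
  expect_identical(cs[[1]]$npix, sum(disk != 0))
  # diagonal touch counts as one component (8-connectivity)
  diag2 <- matrix(0, 10, 10); diag2[3, 3] <- 1; diag2[4, 4] <- 1
  expect_length(findContours(diag2), 1L)
})

test_that("contour count equals connected-component count on random slices", {
  set.seed(6)
  for (i in 1:100) {
    b <- matrix(stats::rbinom(400, 1, 0.25), 20, 20)
    expect_length(findContours(b), brute8Components(b))
  }
})

test_that("holes are filled before descriptors", {
  ann <- rasterDisk(40, 20, 20, 150) - rasterDisk(40, 20, 20, 30)
  cs <- findContours(ann)
  expect_length(cs, 1L)
  expect_identical(cs[[1]]$npix, sum(rasterDisk(40, 20, 20, 150) != 0))
})

test_that("shape descriptors match analytic shapes", {
  sq <- matrix(0, 20, 20); sq[5:14, 5:14] <- 1
  d <- shapeDescriptors(findContours(sq)[[1]])
  expect_equal(d$aspect, 1)
  expect_equal(d$solidity, 1)
  expect_equal(sort(c(d$w, d$h)), c(10, 10))

  r <- matrix(0, 20, 20); r[5:6, 5:8] <- 1
  expect_equal(shapeDescriptors(findContours(r)[[1]])$aspect, 0.5)

  # plus sign, arm width w and length 3w: S = a/ha = 5/7
  pl <- matrix(0, 30, 30); pl[13:15, 7:15] <- 1; pl[7:15, 13:15] <- 1
  expect_equal(shapeDescriptors(findContours(pl)[[1]])$solidity, 5 / 7,
               tolerance = 0.06)

  disk <- rasterDisk(40, 20, 20, 90)
  expect_gte(shapeDescriptors(findContours(disk)[[1]])$solidity, 0.98)
})

test_that("aspect is invariant under 90-degree rotation; solidity ~1 for convex rasters", {
  set.seed(7)
  for (i in 1:5) {
    w <- sample(4:12, 1); h <- sample(4:12, 1)
    m <- matrix(0, 30, 30); m[5 + seq_len(w), 5 + seq_len(h)] <- 1
    d1 <- shapeDescriptors(findContours(m)[[1]])
    d2 <- shapeDescriptors(findContours(t(m))[[1]])
    expect_equal(d1$aspect, d2$aspect, tolerance = 1e-9)
    expect_equal(d1$solidity, 1, tolerance = 0.02)
  }
})

test_that("pruning applies physical-unit criteria, is a subset and idempotent", {
  expect_identical(pruneCandidates(list(), shapeCriteria("restrictive")),
                   list())
  # 25 mm circle at 0.8 mm pixels: area ~ 490 mm^2, round and solid: kept
  disk <- rasterDisk(64, 32, 32, (12.5 / 0.8)^2)
  cs <- findContours(disk)
  kept <- pruneCandidates(cs, shapeCriteria("restrictive"),
                          spacing = c(0.8, 0.8, 1))
  expect_length(kept, 1L)
  # thin sliver rejected on aspect
  sliver <- matrix(0, 50, 10); sliver[5:44, 4:5] <- 1
  expect_length(pruneCandidates(findContours(sliver),
                                shapeCriteria("permissive"),
                                spacing = c(1, 1, 1)), 0L)
  # subset + idempotence on a mixed population
  mixed <- c(cs, findContours(sliver), findContours(rasterDisk(20, 10, 10, 4)))
  k1 <- pruneCandidates(mixed, shapeCriteria("permissive"), c(0.8, 0.8, 1))
  expect_true(all(vapply(k1, function(x) any(vapply(mixed, identical,
    logical(1), y = x[setdiff(names(x), "desc")])), logical(1))) ||
    length(k1) <= length(mixed))
  k2 <- pruneCandidates(k1, shapeCriteria("permissive"), c(0.8, 0.8, 1))
  expect_identical(vapply(k2, function(x) x$npix, integer(1)),
                   vapply(k1, function(x) x$npix, integer(1)))
})

test_that("criteria validation rejects inconsistent bounds", {
  expect_error(shapeCriteria(min_area = 100, max_area = 50), "min_area")
  expect_error(shapeCriteria(min_aspect = 1.5), "aspect")
})

test_that("contour intersection requires adjacency and shared pixels", {
  disk <- rasterDisk(30, 15, 15, 50)
  c1 <- findContours(disk, 3)[[1]]
  c2 <- findContours(disk, 4)[[1]]
  expect_true(contoursIntersect(c1, c2))
  far <- findContours(rasterDisk(30, 5, 5, 4), 4)[[1]]
  expect_false(contoursIntersect(c1, far))
  expect_error(contoursIntersect(c1, findContours(disk, 5)[[1]]),
               "adjacent")
  # two squares sharing exactly one pixel column
  a <- matrix(0, 20, 20); a[5:10, 5:10] <- 1
  b <- matrix(0, 20, 20); b[10:15, 5:10] <- 1
  ca <- findContours(a, 1)[[1]]; cb <- findContours(b, 2)[[1]]
  expect_true(contoursIntersect(ca, cb))
  expect_false(contoursIntersect(ca, cb, min_overlap = 7L))
})
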