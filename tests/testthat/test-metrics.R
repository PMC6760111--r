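test_that("confusion counts and Hausdorff agree with exhaustive oracles", {
  set.seed(20)
  for (i in 1:25) {
    p <- randomMaskPair(dims = c(6, 6, 6), p = 0.3,
                        spacing = c(0.7, 1.1, 2.0))
    cc <- confusionCounts(p$a, p$b)
    bc <- bruteConfusion(as.vector(p$arrA), as.vector(p$arrB))
    expect_identical(cc[c("TP", "FP", "FN", "TN")],
                     bc[c("TP", "FP", "FN", "TN")])
    if (sum(p$arrA) && sum(p$arrB)) {
      expect_equal(hausdorffDistance(p$a, p$b),
                   bruteHausdorff(p$arrA, p$arrB, c(0.7, 1.1, 2.0)),
                   tolerance = 1e-12)
    }
  }
})

test_that("Dice and Jaccard follow their printed formulas and relation", {
  a <- array(0L, c(4, 4, 1)); a[1:2, 1:2, 1] <- 1L   # |R1| = 4
  b <- array(0L, c(4, 4, 1)); b[2:3, 1:2, 1] <- 1L   # |R2| = 4, overlap 2
  A <- BinaryMask3D(a); B <- BinaryMask3D(b)
  expect_equal(diceCoefficient(A, B), 0.5)
  expect_equal(jaccardIndex(A, B), 1 / 3)
  expect_equal(diceCoefficient(A, A), 1)
  expect_equal(jaccardIndex(A, A), 1)
  disj <- BinaryMask3D(array(0L, c(4, 4, 1)) + 0L)
  v <- voxels(disj); v[4, 4, 1] <- 1L
  disj <- BinaryMask3D(v)
  expect_equal(diceCoefficient(A, disj), 0)
  expect_equal(jaccardIndex(A, disj), 0)
})

test_that("JAC = DSC/(2-DSC) and JAC <= DSC on random pairs", {
  set.seed(21)
  for (i in 1:200) {
    p <- randomMaskPair(dims = c(5, 5, 5), p = stats::runif(1, 0.1, 0.6))
    dsc <- diceCoefficient(p$a, p$b)
    jac <- jaccardIndex(p$a, p$b)
    expect_equal(jac, dsc / (2 - dsc), tolerance = 1e-12)
    expect_lte(jac, dsc + 1e-15)
    if (jac == dsc) expect_true(dsc %in% c(0, 1))
  }
})

test_that("rates follow the formulas; undefined denominators give NA", {
  r <- overlapRates(list(TP = 2, FP = 1, FN = 3, TN = 10))
  expect_equal(unname(r["sensitivity"]), 0.4)
  expect_equal(unname(r["specificity"]), 10 / 11)
  expect_equal(unname(r["vs"]), 1 - 2 / 8)
  perfect <- overlapRates(list(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_true(all(perfect == 1))
  balanced <- overlapRates(list(TP = 4, FP = 3, FN = 3, TN = 2))
  expect_equal(unname(balanced["vs"]), 1)
  none <- overlapRates(list(TP = 0, FP = 0, FN = 0, TN = 8))
  expect_true(is.na(none["sensitivity"]))
})

test_that("Hausdorff distance is metric-like and respects spacing", {
  a <- array(0L, c(6, 6, 6)); a[1, 1, 1] <- 1L
  b <- array(0L, c(6, 6, 6)); b[1, 4, 5] <- 1L
  A <- BinaryMask3D(a); B <- BinaryMask3D(b)
  expect_equal(hausdorffDistance(A, B), 5)      # 3-4-5 triangle
  expect_equal(hausdorffDistance(A, A), 0)
  expect_equal(hausdorffDistance(A, B), hausdorffDistance(B, A))
  Amm <- BinaryMask3D(a, spacing = c(1, 2, 0.5))
  Bmm <- BinaryMask3D(b, spacing = c(1, 2, 0.5))
  expect_equal(hausdorffDistance(Amm, Bmm), sqrt(36 + 4))
  expect_error(hausdorffDistance(A, BinaryMask3D(array(0L, c(6, 6, 6)))),
               "empty")
})

test_that("unit-interval metrics are invariant under axis permutation of both masks", {
  set.seed(22)
  p <- randomMaskPair(dims = c(5, 6, 7))
  perm <- aperm(voxels(p$a), c(3, 1, 2))
  permB <- aperm(voxels(p$b), c(3, 1, 2))
  expect_equal(diceCoefficient(p$a, p$b),
               diceCoefficient(BinaryMask3D(perm), BinaryMask3D(permB)))
  expect_equal(jaccardIndex(p$a, p$b),
               jaccardIndex(BinaryMask3D(perm), BinaryMask3D(permB)))
})

test_that("both-empty masks compare as complete overlap, with a warning", {
  e <- BinaryMask3D(array(0L, c(3, 3, 3)))
  expect_warning(d <- diceCoefficient(e, e), "empty")
  expect_equal(d, 1)
  expect_warning(j <- jaccardIndex(e, e), "empty")
  expect_equal(j, 1)
})

test_that("per-slice surfaces and their correlation behave as documented", {
  m <- array(0L, c(10, 10, 5))
  m[1:10, 1:10, 2] <- 1L      # 100 voxels
  m[1:5, 1:4, 3] <- 1L        # 20 voxels
  m[1:2, 1:2, 4] <- 1L        # 4 voxels
  mask <- BinaryMask3D(m, spacing = c(0.5, 0.5, 1))
  s <- perSliceSurfaces(mask)
  expect_equal(s$surface, c(0, 25, 5, 1, 0))
  expect_equal(surfaceCorrelation(s, s), 1)
  # fewer than 3 non-empty paired slices: undefined
  expect_true(is.na(surfaceCorrelation(s[2:3, ], s[2:3, ])))
})

test_that("perturbed surfaces stay highly correlated", {
  ph <- ringFixture()
  s <- perSliceSurfaces(ph$truth$lumen)
  set.seed(23)
  pert <- s
  pert$surface <- pert$surface * stats::runif(nrow(pert), 0.95, 1.05)
  expect_gt(surfaceCorrelation(s, pert), 0.95)
})

test_that("the full metric report is internally consistent", {
  set.seed(24)
  p <- randomMaskPair(dims = c(8, 8, 8), p = 0.4)
  rep <- evaluateSegmentation(p$a, p$b)
  expect_s3_class(rep, "MetricsReport")
  expect_equal(rep$jac, rep$dsc / (2 - rep$dsc), tolerance = 1e-12)
  cc <- rep$counts
  expect_identical(cc$TP + cc$FP + cc$FN + cc$TN, 512L)
  expect_error(evaluateSegmentation(p$a,
    BinaryMask3D(array(0L, c(4, 4, 4)))), "shape")
})
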