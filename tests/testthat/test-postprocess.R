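test_that("labelComponents matches the flood-fill oracle exhaustively on 3x3x1", {
  for (code in 0:511) {
    arr <- array(as.logical(bitwAnd(code, 2^(0:8))), c(3, 3, 1))
    for (conn in c(6L, 26L)) {
      got <- labelComponents(BinaryMask(arr, 1), conn)$labels
      want <- oracleFloodFill(arr, conn)
      expect_true(samePartition(got, want),
                  label = sprintf("code %d conn %d", code, conn))
    }
  }
})

test_that("labelComponents matches the oracle on random 8^3 grids", {
  set.seed(100)
  for (i in 1:100) {
    arr <- array(runif(512) < runif(1, 0.05, 0.5), c(8, 8, 8))
    conn <- sample(c(6L, 18L, 26L), 1)
    got <- labelComponents(BinaryMask(arr, 0.5), conn)$labels
    expect_true(samePartition(got, oracleFloodFill(arr, conn)))
  }
})

test_that("connectivity semantics: face vs corner adjacency", {
  arr <- array(FALSE, c(4, 4, 4))
  arr[2, 2, 2] <- TRUE; arr[3, 2, 2] <- TRUE        # face neighbours
  expect_equal(nrow(labelComponents(BinaryMask(arr, 1), 6)$components), 1L)
  arr2 <- array(FALSE, c(4, 4, 4))
  arr2[2, 2, 2] <- TRUE; arr2[3, 3, 3] <- TRUE      # corner neighbours
  expect_equal(nrow(labelComponents(BinaryMask(arr2, 1), 6)$components), 2L)
  expect_equal(nrow(labelComponents(BinaryMask(arr2, 1), 26)$components), 1L)
  empty <- labelComponents(BinaryMask(array(FALSE, c(3, 3, 3)), 1), 26)
  expect_equal(nrow(empty$components), 0L)
})

test_that("volume filter boundary: exactly 300 mm^3 survives, one voxel less not", {
  # 40 x 30 x 16 block = 19200 voxels at 0.25 mm = 300.0 mm^3
  arr <- array(FALSE, c(42, 32, 18))
  arr[1:40, 1:30, 1:16] <- TRUE
  m <- BinaryMask(arr, 0.25)
  comps <- labelComponents(m, 26)$components
  expect_equal(comps$voxelCount, 19200L)
  expect_equal(comps$volumeMm3, 300)
  expect_equal(nrow(filterByVolume(comps, 0.3)), 1L)   # kept at the boundary
  arr[40, 30, 16] <- FALSE                             # 19199 voxels
  comps2 <- labelComponents(BinaryMask(arr, 0.25), 26)$components
  expect_equal(nrow(filterByVolume(comps2, 0.3)), 0L)  # 299.98 mm^3 removed
  expect_equal(nrow(filterByVolume(comps2, 0)), 1L)    # zero threshold keeps all
})

test_that("calibrateThreshold maximises Youden with midpoint candidates", {
  # perfectly separated: optimum at the 0.5 midpoint
  cal <- calibrateThreshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(tStar(cal), 0.5)
  # two points
  expect_equal(tStar(calibrateThreshold(c(0.3, 0.7), c(0, 1))), 0.5)
  # label-independent probabilities: Youden index near zero at n = 1000
  set.seed(21)
  p <- runif(1000); y <- rbinom(1000, 1, 0.5)
  cal3 <- calibrateThreshold(p, y)
  t3 <- tStar(cal3)
  J <- mean(p[y == 1] > t3) + mean(p[y == 0] <= t3) - 1
  expect_lte(abs(J), 0.15)
  expect_error(calibrateThreshold(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("rescaleProbability anchors {0, t*, 1} and is monotone bijective", {
  cal5 <- methods::new("CalibrationMap", tStar = 0.5)
  p <- seq(0, 1, by = 0.01)
  expect_equal(rescaleProbability(p, cal5), p)                 # identity at 0.5
  cal6 <- methods::new("CalibrationMap", tStar = 0.6)
  expect_equal(rescaleProbability(0.8, cal6), 0.75)            # 0.5 + 0.5*0.2/0.4
  for (t in c(0.05, 0.3, 0.6, 0.95)) {
    cal <- methods::new("CalibrationMap", tStar = t)
    expect_equal(rescaleProbability(t, cal), 0.5)
    out <- rescaleProbability(p, cal)
    expect_equal(out[1], 0); expect_equal(out[length(out)], 1)
    expect_true(all(diff(out) > 0))                            # strictly increasing
  }
  expect_error(rescaleProbability(1.2, cal5), "\\[0,1\\]")
})

test_that("dilation and tooth intersection match the brute-force oracle", {
  set.seed(31)
  arr <- array(runif(1000) < 0.05, c(10, 10, 10))
  for (conn in c(6L, 26L)) for (r in 1:2) {
    got <- dilateMask(BinaryMask(arr, 0.5), r, conn)
    expect_equal(voxelData(got), oracleDilate(arr, r, conn))
  }
  # lesion 2 voxels outside the tooth surface: removed at radius 1, kept at 2
  tooth <- array(FALSE, c(10, 10, 10)); tooth[3:6, 3:6, 3:6] <- TRUE
  lesion <- array(FALSE, c(10, 10, 10)); lesion[8, 4, 4] <- TRUE
  keep1 <- intersectWithTooth(BinaryMask(lesion, 1), BinaryMask(tooth, 1), 1)
  keep2 <- intersectWithTooth(BinaryMask(lesion, 1), BinaryMask(tooth, 1), 2)
  expect_false(any(voxelData(keep1)))
  expect_true(voxelData(keep2)[8, 4, 4])
  # lesion inside the tooth is unchanged (dilation is extensive)
  inner <- array(FALSE, c(10, 10, 10)); inner[4, 4, 4:5] <- TRUE
  expect_identical(voxelData(intersectWithTooth(BinaryMask(inner, 1),
                                                BinaryMask(tooth, 1), 1)), inner)
  # empty tooth mask blanks everything
  expect_false(any(voxelData(intersectWithTooth(
    BinaryMask(lesion, 1), BinaryMask(array(FALSE, c(10, 10, 10)), 1), 1))))
})

test_that("runPostprocess end-to-end examples", {
  d <- c(16, 16, 16)
  tooth <- array(FALSE, d); tooth[4:13, 4:13, 4:13] <- TRUE
  toothMask <- BinaryMask(tooth, 0.25)
  prob <- array(0, d); prob[6:10, 6:10, 6:9] <- 0.9          # 100-voxel blob
  pred <- methods::new("CariesPrediction", lesionProb = prob, toothProb = 0.7)
  # default 0.3 cm^3 threshold swallows a small blob (1.56 mm^3)
  res <- runPostprocess(pred, toothMask, pipelineConfig(inputShape = d))
  expect_false(any(voxelData(res$lesionMask)))
  # tiny threshold keeps it intact
  cfg <- pipelineConfig(inputShape = d, minLesionVolumeCm3 = 1e-4)
  res2 <- runPostprocess(pred, toothMask, cfg)
  expect_identical(voxelData(res2$lesionMask), prob >= 0.5)
  expect_equal(res2$components$voxelCount, 100L)
  # all-zero probabilities: empty mask, no components
  predZ <- methods::new("CariesPrediction", lesionProb = array(0, d), toothProb = 0)
  resZ <- runPostprocess(predZ, toothMask, cfg)
  expect_false(any(voxelData(resZ$lesionMask)))
  expect_equal(nrow(resZ$components), 0L)
  # tooth probability goes through the calibration map
  cal <- methods::new("CalibrationMap", tStar = 0.6)
  res3 <- runPostprocess(pred, toothMask, cfg, cal)
  expect_equal(res3$toothProb, 0.5 + 0.5 * (0.7 - 0.6) / 0.4)
})

test_that("postprocess invariants hold on 200 random masks (seeded)", {
  set.seed(77)
  cfg <- pipelineConfig(inputShape = c(8L, 8L, 8L), minLesionVolumeCm3 = 4e-4,
                        dilationRadiusVoxels = 1L)
  minMm3 <- cfg@minLesionVolumeCm3 * 1000
  for (i in 1:200) {
    prob <- array(runif(512), c(8, 8, 8))
    tooth <- array(runif(512) < 0.4, c(8, 8, 8))
    toothMask <- BinaryMask(tooth, 0.25)
    pred <- methods::new("CariesPrediction", lesionProb = prob,
                         toothProb = runif(1))
    res <- runPostprocess(pred, toothMask, cfg)
    final <- voxelData(res$lesionMask)
    dil <- voxelData(dilateMask(toothMask, 1, cfg@connectivity))
    expect_false(any(final & !dil))                       # containment
    if (nrow(res$components))
      expect_true(all(res$components$volumeMm3 >= minMm3))
    # idempotence: feed the final mask back as a {0,1} probability grid
    again <- runPostprocess(methods::new("CariesPrediction",
                                         lesionProb = final + 0,
                                         toothProb = res$toothProb),
                            toothMask, cfg)
    expect_identical(voxelData(again$lesionMask), final)
  }
})
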