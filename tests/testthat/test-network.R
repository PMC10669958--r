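test_that("network construction validates shapes and scales as expected", {
  expect_error(buildNetwork(networkConfig(nLevels = 4), c(96, 64, 60)),
               "configuration error")
  net <- buildNetwork(networkConfig(nLevels = 4, baseChannels = 2), c(96, 64, 64))
  expect_s3_class(net, "cariesNet")
  # doubling base channels roughly quadruples the conv parameter count
  convCount <- function(bc) {
    n <- buildNetwork(networkConfig(nLevels = 3, baseChannels = bc), c(32, 32, 32))
    sum(vapply(n$params[grepl("\\.W$|\\.W2$", names(n$params))], length, numeric(1)))
  }
  ratio <- convCount(4) / convCount(2)
  expect_gt(ratio, 3); expect_lt(ratio, 4.5)
})

test_that("forward pass emits valid probabilities for random weights and inputs", {
  set.seed(90)
  for (trial in 1:100) {
    net <- buildNetwork(networkConfig(nLevels = 2, baseChannels = 2,
                                      seed = trial), c(8, 8, 8))
    x <- array(rnorm(512, sd = runif(1, 0.5, 3)), c(8, 8, 8))
    fw <- cbctCaries:::.netForward(net, x)
    expect_equal(dim(fw$lesionProb), c(8L, 8L, 8L))
    expect_true(all(fw$lesionProb >= 0 & fw$lesionProb <= 1))
    expect_gte(fw$toothProb, 0); expect_lte(fw$toothProb, 1)
    # attention coefficients clamped to [0, 1]
    expect_gte(fw$coefRange[1], 0); expect_lte(fw$coefRange[2], 1)
  }
})

test_that("predictCaries returns a valid CariesPrediction of the input shape", {
  net <- buildNetwork(networkConfig(nLevels = 3, baseChannels = 2), c(32, 32, 32))
  s <- makeTrainingSample(1)
  pr <- predictCaries(net, s$volume)
  expect_s4_class(pr, "CariesPrediction")
  expect_equal(dim(pr@lesionProb), c(32L, 32L, 32L))
  expect_error(predictCaries(net, VoxelVolume(array(0, c(16, 16, 16)), 0.4)),
               "shape")
})

test_that("deep supervision on/off changes only the head topology", {
  for (ds in c(TRUE, FALSE)) {
    net <- buildNetwork(networkConfig(nLevels = 3, baseChannels = 2,
                                      deepSupervision = ds, seed = 4), c(16, 16, 16))
    fw <- cbctCaries:::.netForward(net, array(rnorm(16^3), c(16, 16, 16)))
    expect_equal(dim(fw$lesionProb), c(16L, 16L, 16L))
  }
  # attention gates off also preserves output shapes
  netNoAtt <- buildNetwork(networkConfig(nLevels = 3, baseChannels = 2,
                                         attentionGates = FALSE, seed = 4),
                           c(16, 16, 16))
  fw <- cbctCaries:::.netForward(netNoAtt, array(rnorm(16^3), c(16, 16, 16)))
  expect_equal(dim(fw$lesionProb), c(16L, 16L, 16L))
})

test_that("attention gate: coefficient per voxel in [0,1], multiplicative, shape-checked", {
  set.seed(13)
  skip_ <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  gate <- array(rnorm(4 * 4 * 4 * 5), c(4, 4, 4, 5))
  out <- attentionGate(skip_, gate, seed = 2)
  expect_equal(dim(out$gated), dim(skip_))
  expect_equal(dim(out$coefficients), c(8L, 8L, 8L))   # one scalar per voxel
  expect_true(all(out$coefficients >= 0 & out$coefficients <= 1))
  # zero skip features give zero output regardless of coefficients
  outZ <- attentionGate(array(0, dim(skip_)), gate, seed = 2)
  expect_true(all(outZ$gated == 0))
  # gated = skip * coef broadcast over channels
  for (c_ in 1:3)
    expect_equal(out$gated[, , , c_], skip_[, , , c_] * out$coefficients)
  expect_error(attentionGate(skip_, array(0, c(3, 4, 4, 5))), "shape error")
})

test_that("segmentation loss has the documented closed-form values", {
  t <- array(c(rep(1, 20), rep(0, 44)), c(4, 4, 4))
  # perfect prediction: loss bounded near 0 by the epsilon clipping
  expect_lt(segmentationLoss(t + 0, t), 1e-5)
  # uniform 0.5 prediction: cross-entropy term is exactly ln 2
  p5 <- array(0.5, c(4, 4, 4))
  I <- sum(0.5 * t); U <- sum(p5) + sum(t) - I
  jacTerm <- 1 - (I + 1e-6) / (U + 1e-6)
  expect_equal(segmentationLoss(p5, t), jacTerm + log(2), tolerance = 1e-12)
  # empty target, empty prediction: Jaccard term 0 by the epsilon convention
  z <- array(0, c(4, 4, 4))
  expect_lt(segmentationLoss(z, z), 1e-6)
  expect_error(segmentationLoss(array(0.3, c(4, 4, 4)), array(0.5, c(4, 4, 4))),
               "binary")
  expect_error(segmentationLoss(array(0.3, c(4, 4, 4)), array(0, c(2, 2, 2))),
               "shape")
})

test_that("analytic gradients match finite differences for every parameter group", {
  set.seed(3)
  net <- buildNetwork(networkConfig(nLevels = 3, baseChannels = 2, seed = 7),
                      c(8, 8, 8))
  x <- array(rnorm(512), c(8, 8, 8))
  t <- as.numeric(array(runif(512) < 0.2, c(8, 8, 8)))
  lossAt <- function(n) {
    fw <- cbctCaries:::.netForward(n, x, training = TRUE)
    lg <- cbctCaries:::.lossAndGrad(fw, t, 1)
    lg$segLoss + lg$clsLoss
  }
  fw <- cbctCaries:::.netForward(net, x, training = TRUE)
  lg <- cbctCaries:::.lossAndGrad(fw, t, 1)
  g <- cbctCaries:::.netBackward(net, fw, matrix(lg$dLogits, ncol = 1), lg$dCls)
  # gradient flows to every parameter group (no dead branches)
  norms <- vapply(names(net$params),
                  function(nm) sqrt(sum(as.vector(g[[nm]])^2)), numeric(1))
  expect_true(all(norms > 0))
  eps <- 1e-5
  set.seed(11)
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      n1 <- net; n1$params[[nm]][i] <- p[i] + eps
      n2 <- net; n2$params[[nm]][i] <- p[i] - eps
      fd <- (lossAt(n1) - lossAt(n2)) / (2 * eps)
      an <- as.vector(g[[nm]])[i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("training is reproducible and rejects degenerate inputs", {
  s <- makeTrainingSample(1)
  ds <- list(s, makeTrainingSample(2))
  net0 <- buildNetwork(tinyNetConfig(seed = 5), c(32, 32, 32))
  n1 <- trainNetwork(net0, ds, steps = 3, seed = 42)
  n2 <- trainNetwork(net0, ds, steps = 3, seed = 42)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$params, n2$params)
  expect_error(trainNetwork(net0, list(), steps = 1), "nonempty")
})

test_that("checkpoints round-trip the network and its config sidecar", {
  net <- buildNetwork(networkConfig(nLevels = 2, baseChannels = 2, seed = 9),
                      c(8, 8, 8))
  f <- tempfile(fileext = ".rds")
  saveNetwork(net, f)
  expect_true(file.exists(sub("\\.rds$", ".json", f)))
  net2 <- loadNetwork(f)
  expect_identical(net2$params, net$params)
  x <- array(rnorm(512), c(8, 8, 8))
  expect_identical(cbctCaries:::.netForward(net, x)$lesionProb,
                   cbctCaries:::.netForward(net2, x)$lesionProb)
})
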