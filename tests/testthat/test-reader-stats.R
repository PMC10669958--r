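test_that("binarization maps 1-3 to absence and 4-5 to presence", {
  expect_equal(binarizeScore(c(1, 3, 4, 5, 2)),
               c("absence", "absence", "presence", "presence", "absence"))
  expect_error(binarizeScore(6), "range")
  expect_error(binarizeScore(0), "range")
})

test_that("published confusion counts reproduce the printed metrics to 3 dp", {
  counts <- readerCounts()
  for (r in seq_len(nrow(counts))) {
    cc <- confusionCounts(TP = counts$TP[r], FP = counts$FP[r],
                          TN = counts$TN[r], FN = counts$FN[r])
    m <- classificationMetrics(cc)
    expect_equal(round(m[["sensitivity"]], 3), counts$sensitivity[r])
    expect_equal(round(m[["specificity"]], 3), counts$specificity[r])
    expect_equal(round(m[["accuracy"]], 3), counts$accuracy[r])
    expect_equal(round(cohensKappa(cc), 3), counts$kappa[r])
  }
})

test_that("metric edge cases: perfect observer and zero denominators", {
  cc <- confusionCounts(TP = 40, FP = 0, TN = 60, FN = 0)
  expect_equal(unname(classificationMetrics(cc)), c(1, 1, 1))
  expect_equal(cohensKappa(cc), 1)
  noPos <- confusionCounts(TP = 0, FP = 2, TN = 8, FN = 0)
  expect_warning(m <- classificationMetrics(noPos), "sensitivity")
  expect_true(is.nan(m[["sensitivity"]]))
})

test_that("kappa family is invariant to category relabeling and flips symmetrically", {
  cc <- confusionCounts(TP = 4377, FP = 257, TN = 13671, FN = 1631)
  swapped <- confusionCounts(TP = 13671, FP = 1631, TN = 4377, FN = 257)
  expect_equal(cohensKappa(cc), cohensKappa(swapped))
  # flipping every binarized rating swaps TP<->FN and TN<->FP
  flipped <- confusionCounts(TP = 1631, FP = 13671, TN = 257, FN = 4377)
  po <- (1631 + 257) / 19936
  expect_equal(cohensKappa(flipped),
               (po - ((1631 + 13671) * 6008 + (257 + 4377) * 13928) / 19936^2) /
                 (1 - ((1631 + 13671) * 6008 + (257 + 4377) * 13928) / 19936^2))
  set.seed(5)
  a <- sample(1:5, 200, TRUE); b <- sample(1:5, 200, TRUE)
  expect_equal(weightedKappa(a, b, "quadratic"), weightedKappa(6 - a, 6 - b, "quadratic"))
  expect_equal(cohensKappa(a, b, categories = 1:5),
               cohensKappa(6 - a, 6 - b, categories = 1:5))
})

test_that("weighted kappa equals the brute-force double sum and degenerates to Cohen", {
  set.seed(41)
  a <- sample(1:5, 300, TRUE, prob = c(0.4, 0.2, 0.1, 0.1, 0.2))
  b <- pmin(5, pmax(1, a + sample(-1:1, 300, TRUE)))
  tab <- table(factor(a, levels = 1:5), factor(b, levels = 1:5))
  expect_equal(weightedKappa(a, b, "quadratic", 1:5), oracleWeightedKappa(tab, 2))
  expect_equal(weightedKappa(a, b, "linear", 1:5), oracleWeightedKappa(tab, 1))
  expect_equal(weightedKappa(a, a, "linear", 1:5), 1)
  expect_equal(weightedKappa(a, a, "quadratic", 1:5), 1)
  # binary scale: any weighting equals Cohen's kappa
  x <- binarizeScore(a); y <- binarizeScore(b)
  lv <- c("absence", "presence")
  expect_equal(weightedKappa(x, y, "quadratic", lv), cohensKappa(x, y, lv))
  expect_equal(weightedKappa(x, y, "linear", lv), cohensKappa(x, y, lv))
})

test_that("Fleiss kappa: identity, null simulation and worked 10-item example", {
  ident <- cbind(c(3, 0, 3, 0, 3), c(0, 3, 0, 3, 0))
  expect_equal(fleissKappa(ident)$overall, 1)
  set.seed(55)
  counts <- t(stats::rmultinom(5000, 3, c(0.5, 0.5)))
  expect_lte(abs(fleissKappa(counts)$overall), 0.05)
  set.seed(56)
  ex <- t(stats::rmultinom(10, 3, c(0.3, 0.5, 0.2)))
  fk <- fleissKappa(ex)
  expect_equal(fk$overall, oracleFleiss(ex))
  # per-category formula against the direct sum
  m <- 3; n <- 10
  pj <- colSums(ex) / (n * m); qj <- 1 - pj
  for (j in 1:3) {
    want <- 1 - sum(ex[, j] * (m - ex[, j])) / (n * m * (m - 1) * pj[j] * qj[j])
    expect_equal(unname(fk$perCategory[j]), want)
  }
  expect_error(fleissKappa(rbind(c(2, 1), c(1, 1))), "same number")
})

test_that("ordinal ROC AUC equals brute-force concordance", {
  # separable extremes
  expect_equal(rocAuc(c(5, 5, 1, 1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # 4-item fixture with a tie across classes
  s <- c(5, 4, 4, 1); l <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(rocAuc(s, l)$auc, oracleAuc(s, l))
  # null: scores independent of labels at n = 2000
  set.seed(61)
  s2 <- sample(1:5, 2000, TRUE); l2 <- runif(2000) < 0.4
  expect_lte(abs(rocAuc(s2, l2)$auc - 0.5), 0.03)
  # 100 random small fixtures against the pair-enumeration oracle
  set.seed(62)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    s3 <- sample(1:5, n, TRUE)
    l3 <- runif(n) < 0.5
    if (!any(l3) || all(l3)) l3[1:2] <- c(TRUE, FALSE)
    expect_equal(rocAuc(s3, l3)$auc, oracleAuc(s3, l3))
  }
  expect_error(rocAuc(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("ordinal AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(63)
  s <- sample(1:5, 400, TRUE, prob = c(0.3, 0.2, 0.1, 0.2, 0.2))
  l <- runif(400) < plogis((s - 3) / 1.5)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))))
  expect_equal(rocAuc(s, l)$auc, ref, tolerance = 1e-10)
})

test_that("consensus rule: unanimity labels, disagreement conflicts, counts add up", {
  surf <- expand.grid(case_id = c("c1", "c2"), tooth_fdi = c("36", "37"),
                      surface = c("mesial", "distal"), stringsAsFactors = FALSE)
  mkTab <- function(scores) {
    do.call(rbind, lapply(seq_along(scores), function(o)
      cbind(surf, condition = "intact", observer_id = paste0("O", o),
            arm = "unaided", score = scores[[o]], session = 1L)))
  }
  # 8 surfaces; observer 3 disagrees on surface 2, all agree elsewhere
  s1 <- c(5, 4, 1, 2, 3, 5, 1, 4)
  s2 <- c(4, 5, 2, 1, 1, 4, 3, 5)
  s3 <- c(5, 1, 3, 3, 2, 4, 2, 4)
  tab <- mkTab(list(s1, s2, s3))
  cons <- consensusGroundTruth(tab, "unaided")
  expect_equal(nrow(cons$groundTruth) + nrow(cons$conflicts), 8L)
  expect_equal(nrow(cons$conflicts), 1L)
  expect_equal(cons$conflicts$reason, "disagreement")
  expect_setequal(unique(cons$groundTruth$provenance), "unanimous")
  # labels follow the binarized unanimity
  gt1 <- cons$groundTruth[cons$groundTruth$case_id == "c1" &
                          cons$groundTruth$tooth_fdi == "36" &
                          cons$groundTruth$surface == "mesial", ]
  expect_equal(gt1$label, "presence")
  # a missing observer score routes the surface to conflicts as incomplete
  tab2 <- tab[-1, ]
  cons2 <- consensusGroundTruth(tab2, "unaided")
  expect_true("incomplete" %in% cons2$conflicts$reason)
  expect_equal(nrow(cons2$groundTruth) + nrow(cons2$conflicts), 8L)
})

test_that("adjudication merging covers conflicts and respects unanimity", {
  gt <- data.frame(case_id = "c1", tooth_fdi = "36", surface = "mesial",
                   label = "presence", provenance = "unanimous")
  cf <- data.frame(case_id = c("c1", "c2"), tooth_fdi = "36",
                   surface = c("distal", "mesial"), reason = "disagreement")
  dec <- data.frame(case_id = c("c1", "c2"), tooth_fdi = "36",
                    surface = c("distal", "mesial"),
                    label = c("presence", "absence"))
  out <- mergeAdjudication(gt, cf, dec)
  expect_equal(nrow(out), 3L)
  expect_equal(sum(out$provenance == "adjudicated"), 2L)
  # zero conflicts: output equals input
  out0 <- mergeAdjudication(gt, cf[0, ], dec[0, ])
  expect_equal(out0$label, gt$label)
  # uncovered conflict errors, listing the surface
  expect_error(mergeAdjudication(gt, cf, dec[1, , drop = FALSE]), "cover")
  # decision for a non-conflict surface: warning, unanimity wins
  dec2 <- rbind(dec, data.frame(case_id = "c1", tooth_fdi = "36",
                                surface = "mesial", label = "absence"))
  expect_warning(out2 <- mergeAdjudication(gt, cf, dec2), "unanimity")
  expect_equal(out2$label[out2$case_id == "c1" & out2$surface == "mesial"],
               "presence")
})

test_that("confusion from ratings matches direct counting and the fixture marginals", {
  fx <- makeStudyFixture()
  counts <- readerCounts()
  cc <- confusionFromRatings(fx$ratings, fx$groundTruth, "Observer 1", "unaided")
  expect_equal(c(cc@TP, cc@TN, cc@FP, cc@FN), c(4377L, 13671L, 257L, 1631L))
  cc3 <- confusionFromRatings(fx$ratings, fx$groundTruth, "Observer 3", "aided")
  expect_equal(c(cc3@TP, cc3@TN, cc3@FP, cc3@FN), c(5299L, 12875L, 1053L, 709L))
})

test_that("intra-observer repeatability: identical and one-flip sessions", {
  surf <- data.frame(case_id = sprintf("c%02d", 1:50), tooth_fdi = "36",
                     surface = "mesial", truth = rep(c(TRUE, FALSE), 25))
  set.seed(71)
  scores <- sample(1:5, 50, TRUE)
  two <- function(s2) rbind(
    data.frame(case_id = surf$case_id, tooth_fdi = "36", surface = "mesial",
               condition = "intact", observer_id = "O1", arm = "unaided",
               score = scores, session = 1L),
    data.frame(case_id = surf$case_id, tooth_fdi = "36", surface = "mesial",
               condition = "intact", observer_id = "O1", arm = "unaided",
               score = s2, session = 2L))
  res <- intraObserver(two(scores))
  expect_equal(res$cohenFive, 1)
  expect_equal(res$weightedFiveQuadratic, 1)
  expect_equal(res$cohenBinary, 1)
  # one flipped binary rating equals the hand-computed 2x2 kappa
  s2 <- scores; s2[1] <- if (scores[1] >= 4) 1L else 5L
  res2 <- intraObserver(two(s2))
  b1 <- binarizeScore(scores); b2 <- binarizeScore(s2)
  tab <- table(factor(b1, levels = c("absence", "presence")),
               factor(b2, levels = c("absence", "presence")))
  po <- sum(diag(tab)) / 50
  pe <- sum(rowSums(tab) * colSums(tab)) / 50^2
  expect_equal(res2$cohenBinary, (po - pe) / (1 - pe))
  expect_error(intraObserver(two(scores), subsetCases = character(0)), "empty")
})

test_that("fullReport reproduces the published distribution rows and is deterministic", {
  fx <- makeStudyFixture()
  rep1 <- fullReport(fx$ratings, fx$groundTruth)
  dist <- readerDistribution()
  for (r in which(dist$observer != "Ground Truth")) {
    row <- rep1$distribution[rep1$distribution$observer_id == dist$observer[r] &
                             rep1$distribution$arm == dist$arm[r], ]
    expect_equal(row$absence, dist$absence[r])
    expect_equal(row$presence, dist$presence[r])
  }
  expect_equal(rep1$groundTruthCounts$absence, 13928)
  expect_equal(rep1$groundTruthCounts$presence, 6008)
  expect_equal(nrow(rep1$performance), 6L)   # one row per observer x arm
  # regenerating from the same inputs gives the identical bundle
  rep2 <- fullReport(fx$ratings, fx$groundTruth)
  expect_identical(rep1$performance, rep2$performance)
  # serialisation writes the CSVs and JSON
  dir <- tempfile()
  writeReportBundle(rep1, dir)
  expect_true(file.exists(file.path(dir, "performance.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
})

test_that("kappa confidence intervals cover the point estimate sensibly", {
  cc <- confusionCounts(TP = 4377, FP = 257, TN = 13671, FN = 1631)
  ci <- cohensKappaCI(cc)
  expect_lt(ci[["lower"]], ci[["kappa"]])
  expect_gt(ci[["upper"]], ci[["kappa"]])
  expect_equal(unname(ci[["kappa"]]), cohensKappa(cc))
  expect_lt(ci[["upper"]] - ci[["lower"]], 0.05)   # large n, tight interval
})
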