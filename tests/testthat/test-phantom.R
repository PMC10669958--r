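test_that("phantom generation is deterministic and respects the spec", {
  spec <- phantomSpec(gridShape = c(48, 48, 36), spacingMm = 0.4, nTeeth = 2,
                      lesions = data.frame(tooth_fdi = "31", surface = "distal",
                                           targetVolumeMm3 = 20),
                      seed = 11)
  ph1 <- generatePhantom(spec)
  ph2 <- generatePhantom(spec)
  expect_identical(voxelData(ph1$volume), voxelData(ph2$volume))
  expect_identical(voxelData(ph1$toothMasks[["31"]]),
                   voxelData(ph2$toothMasks[["31"]]))
  # realized lesion volume within 10% of the 20 mm^3 target
  vol <- maskVolumeMm3(ph1$lesionMasks[["31.distal"]])
  expect_gte(vol, 18); expect_lte(vol, 22)
  # lesion inside its tooth and connected
  les <- ph1$lesionMasks[["31.distal"]]
  expect_false(any(voxelData(les) & !voxelData(ph1$toothMasks[["31"]])))
  comps <- labelComponents(les, 26)
  expect_equal(nrow(comps$components), 1L)
  # truth table marks exactly the requested surface
  tr <- ph1$surfaceTruth
  expect_true(tr$truth[tr$tooth_fdi == "31" & tr$surface == "distal"])
  expect_equal(sum(tr$truth), 1L)
  # all truth masks are valid extraction inputs
  for (id in names(ph1$toothMasks))
    expect_s4_class(ToothEntry(id, ph1$toothMasks[[id]]), "ToothEntry")
})

test_that("noise-free phantom contains exactly the configured intensity levels", {
  spec <- phantomSpec(gridShape = c(32, 32, 24), spacingMm = 0.5, nTeeth = 1,
                      intensity = list(background = 0.1, dentin = 1,
                                       enamel = 1.5, lesionContrast = 0.5),
                      noiseSigma = 0, seed = 2)
  ph <- generatePhantom(spec)
  expect_setequal(unique(as.vector(voxelData(ph$volume))), c(0.1, 1, 1.5))
})

test_that("phantom spec validation rejects impossible lesions", {
  expect_error(phantomSpec(nTeeth = 2,
                           lesions = data.frame(tooth_fdi = "35",
                                                surface = "mesial",
                                                targetVolumeMm3 = 5)),
               "exists")
  expect_error(phantomSpec(lesions = data.frame(tooth_fdi = "31",
                                                surface = "mesial",
                                                targetVolumeMm3 = -1)),
               "> 0")
  spec <- phantomSpec(gridShape = c(32, 32, 24), spacingMm = 0.4, nTeeth = 1,
                      lesions = data.frame(tooth_fdi = "31", surface = "mesial",
                                           targetVolumeMm3 = 1e5), seed = 1)
  expect_error(generatePhantom(spec), "exceeds")
})

test_that("dataset fan-out is reproducible and matches the prevalence", {
  base <- phantomSpec(gridShape = c(32, 32, 24), spacingMm = 0.5, nTeeth = 2,
                      seed = 1)
  d1 <- generateDataset(base, 10, masterSeed = 5, materialize = FALSE)
  d2 <- generateDataset(base, 10, masterSeed = 5, materialize = FALSE)
  expect_identical(d1$manifest, d2$manifest)
  expect_equal(length(unique(d1$manifest$seed)), 10L)
  # binomial check on lesion prevalence: 200 samples x 4 surfaces at p = 0.3
  d3 <- generateDataset(base, 200, masterSeed = 9, lesionPrevalence = 0.3,
                        materialize = FALSE)
  hits <- sum(d3$manifest$nLesions); n <- 200 * 4
  ci <- qbinom(c(0.025, 0.975), n, 0.3)
  expect_gte(hits, ci[1]); expect_lte(hits, ci[2])
})

test_that("simulated observers reproduce their operating characteristics", {
  # perfect observer with extreme confidence equals the truth exactly
  surf <- data.frame(case_id = sprintf("c%03d", 1:200), tooth_fdi = "36",
                     surface = "mesial", truth = runif(200) < 0.4)
  perfect <- observerModel(sensitivity = 1 - 1e-12, specificity = 1 - 1e-12,
                           scorePosCall = c(0, 1), scoreNegCall = c(1, 0, 0))
  tab <- simulateRatingStudy(surf,
    list(unaided = list(O1 = perfect), aided = list(O1 = perfect)), seed = 3)
  sub <- tab[tab$arm == "unaided", ]
  m <- match(paste(sub$case_id), surf$case_id)
  expect_identical(binarizeScore(sub$score) == "presence", surf$truth[m])
  expect_setequal(unique(sub$score), c(1L, 5L))

  # sens 0.85 / spec 0.95 recovered within +-0.01 at 20000 surfaces
  set.seed(4)
  surf2 <- data.frame(case_id = sprintf("s%05d", 1:20000), tooth_fdi = "36",
                      surface = "mesial", truth = runif(20000) < 0.5)
  om <- observerModel(0.85, 0.95)
  tab2 <- simulateRatingStudy(surf2,
    list(unaided = list(O1 = om), aided = list(O1 = om)), seed = 8)
  sub2 <- tab2[tab2$arm == "unaided", ]
  m2 <- match(sub2$case_id, surf2$case_id)
  call <- binarizeScore(sub2$score) == "presence"
  sens <- mean(call[surf2$truth[m2]])
  spec <- mean(!call[!surf2$truth[m2]])
  expect_lte(abs(sens - 0.85), 0.01)
  expect_lte(abs(spec - 0.95), 0.01)

  # identical seeds and models give identical ratings (kappa 1)
  tabA <- simulateRatingStudy(surf, list(unaided = list(O1 = om),
                                         aided = list(O1 = om)), seed = 5)
  tabB <- simulateRatingStudy(surf, list(unaided = list(O1 = om),
                                         aided = list(O1 = om)), seed = 5)
  expect_identical(tabA$score, tabB$score)
  expect_equal(cohensKappa(tabA$score[tabA$arm == "unaided"],
                           tabB$score[tabB$arm == "unaided"],
                           categories = 1:5), 1)
})

test_that("repeat-session records support intra-observer analysis", {
  surf <- data.frame(case_id = sprintf("c%03d", 1:100), tooth_fdi = "36",
                     surface = "mesial", truth = runif(100) < 0.3)
  om <- observerModel(0.9, 0.9)
  tab <- simulateRatingStudy(surf, list(unaided = list(O1 = om),
                                        aided = list(O1 = om)),
                             seed = 6, repeatCases = surf$case_id[1:50])
  expect_equal(sum(tab$session == 2L), 2 * 50)
  res <- intraObserver(tab, subsetCases = surf$case_id[1:50])
  expect_equal(nrow(res), 2L)          # one row per arm
  expect_true(all(res$nPairs == 50))
  expect_true(all(res$cohenFive <= 1 & res$cohenFive >= -1))
})
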