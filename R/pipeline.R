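# Orchestration: YAML run configuration with schema validation, and the
# end-to-end demonstration pipeline chaining phantom generation, tooth
# extraction, training, prediction, post-processing and reader statistics.

.CONFIG_SCHEMA <- list(
  pipeline = c("marginMm", "targetSpacingMm", "inputShape", "minLesionVolumeCm3",
               "dilationRadiusVoxels", "connectivity", "probCutoff", "resizeMode"),
  network = c("nLevels", "baseChannels", "leakySlope", "deepSupervision",
              "attentionGates", "learningRate", "batchSize", "seed"),
  phantom = c("gridShape", "spacingMm", "nTeeth", "crownSemiAxesMm",
              "rootSemiAxesMm", "crownExponent", "intensity", "lesions",
              "noiseSigma", "streakArtifacts", "seed"),
  run = c("outDir", "seed", "trainSamples", "testSamples", "steps",
          "lesionPrevalence", "lesionVolumeRangeMm3", "logLevel")
)

#' Validate a YAML run configuration
#'
#' Reads the file, checks every section against the known schema and value
#' constraints, and reports all violations at once.  Unknown keys produce
#' warnings (forward compatibility), never errors.
#'
#' @param path YAML file
#' @return list with \code{config} (the parsed list, NULL when unreadable) and
#'   \code{violations} (character vector; empty when valid)
#' @export
validateConfig <- function(path) {
  if (!file.exists(path))
    return(list(config = NULL, violations = sprintf("file not found: %s", path)))
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    structure(list(), parseError = conditionMessage(e)))
  if (!is.null(attr(cfg, "parseError")))
    return(list(config = NULL,
                violations = paste("YAML parse error:", attr(cfg, "parseError"))))
  v <- character()
  for (sec in names(cfg)) {
    if (!sec %in% names(.CONFIG_SCHEMA)) {
      warning(sprintf("unknown configuration section '%s' ignored", sec))
      next
    }
    unknown <- setdiff(names(cfg[[sec]]), .CONFIG_SCHEMA[[sec]])
    if (length(unknown))
      warning(sprintf("unknown key(s) in section '%s': %s", sec,
                      paste(unknown, collapse = ", ")))
  }
  p <- cfg$pipeline
  chkPos <- function(x, nm, sec) {
    if (!is.null(x) && (!is.numeric(x) || any(x <= 0)))
      v <<- c(v, sprintf("%s.%s must be positive", sec, nm))
  }
  if (!is.null(p)) {
    if (!is.null(p$marginMm) && (!is.numeric(p$marginMm) || p$marginMm < 0))
      v <- c(v, "pipeline.marginMm must be >= 0")
    chkPos(p$targetSpacingMm, "targetSpacingMm", "pipeline")
    chkPos(p$inputShape, "inputShape", "pipeline")
    if (!is.null(p$minLesionVolumeCm3) && p$minLesionVolumeCm3 < 0)
      v <- c(v, "pipeline.minLesionVolumeCm3 must be >= 0")
    if (!is.null(p$connectivity) && !p$connectivity %in% c(6, 18, 26))
      v <- c(v, "pipeline.connectivity must be 6, 18 or 26")
  }
  n <- cfg$network
  if (!is.null(n)) {
    if (!is.null(n$nLevels) && n$nLevels < 2)
      v <- c(v, "network.nLevels must be >= 2")
    chkPos(n$baseChannels, "baseChannels", "network")
    chkPos(n$learningRate, "learningRate", "network")
  }
  ph <- cfg$phantom
  if (!is.null(ph)) {
    chkPos(ph$gridShape, "gridShape", "phantom")
    chkPos(ph$spacingMm, "spacingMm", "phantom")
    if (!is.null(ph$noiseSigma) && ph$noiseSigma < 0)
      v <- c(v, "phantom.noiseSigma must be >= 0")
  }
  list(config = cfg, violations = v)
}

.mergeConfig <- function(defaults, override) {
  for (nm in names(override)) defaults[[nm]] <- override[[nm]]
  defaults
}

.fileChecksums <- function(paths) {
  ok <- file.exists(paths)
  out <- rep(NA_character_, length(paths))
  out[ok] <- unname(tools::md5sum(paths[ok]))
  stats::setNames(out, basename(paths))
}

#' Run the full demonstration pipeline
#'
#' Chains every stage on procedurally generated phantoms: corpus generation,
#' per-tooth extraction into network space, training of a small attention
#' U-Net, prediction and post-processing on held-out phantoms, simulated
#' two-arm reader ratings, consensus ground truth and the full report.  Each
#' stage writes its artifacts under \code{outDir} and the run manifest records
#' inputs, outputs, seeds and MD5 checksums; a rerun with the same
#' configuration reproduces the manifest.
#'
#' @param configPath YAML configuration (see [validateConfig()]); NULL uses the
#'   packaged demo configuration
#' @param outDir output directory (overrides the config)
#' @param seed global seed (overrides the config)
#' @return the manifest (list), invisibly; also written as manifest.json
#' @export
runEndToEnd <- function(configPath = NULL, outDir = NULL, seed = NULL) {
  configPath <- configPath %||% system.file("extdata", "default-config.yaml",
                                            package = "cbctCaries")
  val <- validateConfig(configPath)
  if (length(val$violations))
    stop("invalid configuration:\n  ", paste(val$violations, collapse = "\n  "))
  cfg <- val$config
  run <- cfg$run %||% list()
  outDir <- outDir %||% run$outDir %||% tempfile("cbct-run-")
  seed <- as.integer(seed %||% run$seed %||% 1L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = configPath, seed = seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed (artifacts under %s): %s", name, outDir,
                   conditionMessage(e)), call. = FALSE))
  }

  pcArgs <- cfg$pipeline %||% list()
  pconf <- do.call(pipelineConfig, pcArgs)
  nconf <- do.call(networkConfig, .mergeConfig(list(seed = seed), cfg$network %||% list()))
  phArgs <- .mergeConfig(cfg$phantom %||% list(), list(seed = seed))
  baseSpec <- do.call(phantomSpec, phArgs)
  nTrain <- run$trainSamples %||% 4L
  nTest <- run$testSamples %||% 2L
  steps <- run$steps %||% 30L
  seeds <- .spawnSeeds(seed, 4L)

  phantoms <- stage("phantom", {
    ds <- generateDataset(baseSpec, nTrain + nTest, masterSeed = seeds[1],
                          lesionPrevalence = run$lesionPrevalence %||% 0.5,
                          lesionVolumeRangeMm3 =
                            unlist(run$lesionVolumeRangeMm3 %||% c(8, 25)))
    utils::write.csv(ds$manifest, file.path(outDir, "phantom-manifest.csv"),
                     row.names = FALSE)
    ds
  })

  extracted <- stage("extract", {
    lapply(phantoms$samples, function(s) {
      id <- names(s$toothMasks)[1]
      tooth <- ToothEntry(id, s$toothMasks[[id]])
      ex <- extractToothVolume(s$volume, tooth, pconf)
      lesion <- Reduce(`|`, lapply(s$lesionMasks, voxelData),
                       array(FALSE, dim(s$volume@data)))
      lesionNet <- applyCropTransform(
        BinaryMask(lesion, voxelSpacing(s$volume)), ex$transform)
      list(volume = ex$toothVolume, toothMask = ex$toothMask,
           lesionMask = lesionNet, transform = ex$transform,
           label = any(lesionNet@data),
           truth = s$surfaceTruth)
    })
  })

  net <- stage("train", {
    trainSet <- lapply(extracted[seq_len(nTrain)], function(e)
      list(volume = e$volume, lesionMask = e$lesionMask, label = e$label))
    net0 <- buildNetwork(nconf, pconf@inputShape)
    net <- trainNetwork(net0, trainSet, steps = steps, seed = seeds[2])
    saveNetwork(net, file.path(outDir, "checkpoint.rds"))
    utils::write.csv(net$history, file.path(outDir, "loss-history.csv"),
                     row.names = FALSE)
    net
  })

  preds <- stage("predict", {
    lapply(extracted[nTrain + seq_len(nTest)], function(e) {
      pr <- predictCaries(net, e$volume)
      pp <- runPostprocess(pr, e$toothMask, pconf)
      list(prediction = pr, post = pp,
           jaccard = softJaccard(pr@lesionProb, e$lesionMask))
    })
  })

  report <- stage("readers", {
    truth <- do.call(rbind, lapply(phantoms$samples, `[[`, "surfaceTruth"))
    obs <- list(
      unaided = list(R1 = observerModel(0.75, 0.95), R2 = observerModel(0.78, 0.93),
                     R3 = observerModel(0.76, 0.75)),
      aided = list(R1 = observerModel(0.88, 0.96), R2 = observerModel(0.87, 0.96),
                   R3 = observerModel(0.88, 0.92)))
    ratings <- simulateRatingStudy(truth, obs, seed = seeds[3])
    cons <- consensusGroundTruth(ratings, "unaided")
    decisions <- cons$conflicts
    if (nrow(decisions)) {
      key <- .surfaceKey(decisions)
      tkey <- .surfaceKey(truth)
      decisions$label <- ifelse(truth$truth[match(key, tkey)], "presence", "absence")
    } else decisions$label <- character()
    gt <- mergeAdjudication(cons$groundTruth, cons$conflicts, decisions)
    rep_ <- fullReport(ratings, gt)
    writeReportBundle(rep_, file.path(outDir, "report"))
    utils::write.csv(ratings, file.path(outDir, "ratings.csv"), row.names = FALSE)
    rep_
  })

  manifest$stages <- list(
    phantom = list(samples = nTrain + nTest, seed = seeds[1],
                   files = as.list(.fileChecksums(file.path(outDir, "phantom-manifest.csv")))),
    train = list(steps = steps, seed = seeds[2],
                 finalLoss = utils::tail(net$history$loss, 1),
                 files = as.list(.fileChecksums(file.path(outDir, "loss-history.csv")))),
    predict = list(meanJaccard = mean(vapply(preds, `[[`, numeric(1), "jaccard"))),
    readers = list(seed = seeds[3],
                   files = as.list(.fileChecksums(file.path(outDir, "ratings.csv")))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
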