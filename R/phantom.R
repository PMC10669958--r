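# Seeded procedural tooth phantoms and synthetic reader-rating tables.
#
# A phantom is a row of simplified teeth (fused superellipsoid crown + tapered
# root) along the second array axis, with optional low-intensity ellipsoidal
# lesions capped on the mesial (-axis2) or distal (+axis2) surface, additive
# Gaussian noise and optional streak artifacts.  Every draw is split into
# named RNG substreams (geometry, noise, ratings) so components are
# independently reproducible.

#' Specify a tooth phantom
#'
#' @param gridShape integer length-3 grid extents (axis 1 = tooth long axis,
#'   axis 2 = mesiodistal row axis)
#' @param spacingMm isotropic voxel size, mm
#' @param nTeeth number of teeth in the row
#' @param crownSemiAxesMm,rootSemiAxesMm superellipsoid semi-axes, mm
#' @param crownExponent superellipsoid exponent (2 = ellipsoid, larger = boxier)
#' @param intensity named list: background, dentin, enamel levels plus
#'   lesionContrast (lesion intensity = dentin * (1 - lesionContrast))
#' @param lesions data.frame with columns tooth_fdi, surface ("mesial"/"distal"),
#'   targetVolumeMm3; or NULL
#' @param noiseSigma additive Gaussian noise standard deviation (intensity units)
#' @param streakArtifacts add oriented high-intensity streaks (default FALSE)
#' @param seed integer RNG seed
#' @return a validated phantom specification (list)
#' @export
phantomSpec <- function(gridShape = c(96L, 96L, 64L), spacingMm = 0.25,
                        nTeeth = 3L,
                        crownSemiAxesMm = c(4, 3.5, 3.5),
                        rootSemiAxesMm = c(6, 2.2, 2.2),
                        crownExponent = 4,
                        intensity = list(background = 0, dentin = 1,
                                         enamel = 1.6, lesionContrast = 0.6),
                        lesions = NULL, noiseSigma = 0.05,
                        streakArtifacts = FALSE, seed = 1L) {
  spec <- list(gridShape = as.integer(gridShape), spacingMm = spacingMm,
               nTeeth = as.integer(nTeeth), crownSemiAxesMm = crownSemiAxesMm,
               rootSemiAxesMm = rootSemiAxesMm, crownExponent = crownExponent,
               intensity = intensity, lesions = lesions, noiseSigma = noiseSigma,
               streakArtifacts = isTRUE(streakArtifacts), seed = as.integer(seed))
  .validatePhantomSpec(spec)
  spec
}

.validatePhantomSpec <- function(spec) {
  stopifnot(length(spec$gridShape) == 3L, all(spec$gridShape > 0L),
            spec$spacingMm > 0, spec$nTeeth >= 1L, spec$noiseSigma >= 0)
  ids <- .phantomToothIds(spec$nTeeth)
  if (!is.null(spec$lesions)) {
    les <- spec$lesions
    stopifnot(all(c("tooth_fdi", "surface", "targetVolumeMm3") %in% names(les)))
    if (any(les$targetVolumeMm3 <= 0)) stop("lesion target volumes must be > 0")
    if (!all(les$surface %in% c("mesial", "distal")))
      stop("lesion surface must be 'mesial' or 'distal'")
    if (!all(as.character(les$tooth_fdi) %in% ids))
      stop("lesion tooth_fdi must name a tooth that exists in the phantom")
  }
  invisible(spec)
}

# FDI codes of the phantom teeth: lower-left quadrant 31, 32, ...
.phantomToothIds <- function(nTeeth) as.character(30L + seq_len(nTeeth))

# superellipsoid indicator on voxel-centre grids (mm coordinates)
.superellipsoid <- function(cx, cy, cz, centre, semi, expo) {
  (abs((cx - centre[1]) / semi[1])^expo +
   abs((cy - centre[2]) / semi[2])^expo +
   abs((cz - centre[3]) / semi[3])^expo) <= 1
}

#' Generate a tooth phantom
#'
#' Deterministic given the spec's seed.  Each requested lesion is grown as a
#' sphere centred on the named surface of its tooth and intersected with the
#' tooth mask; the sphere radius is bisected until the realised volume is
#' within 10% of the target (an error is raised when the target exceeds what
#' the tooth can host).
#'
#' @param spec a specification from [phantomSpec()]
#' @param caseId case identifier written into the surface-truth table
#' @return list with \code{volume} ([VoxelVolume-class]), \code{toothMasks}
#'   (named list of [BinaryMask-class] by FDI code), \code{lesionMasks} (named
#'   list by "fdi.surface"), and \code{surfaceTruth} (data.frame case_id,
#'   tooth_fdi, surface, truth, lesionVolumeMm3)
#' @export
generatePhantom <- function(spec, caseId = "case1") {
  .validatePhantomSpec(spec)
  seeds <- .spawnSeeds(spec$seed, 3L)   # geometry, noise, streaks
  d <- spec$gridShape; sp <- spec$spacingMm
  ext <- d * sp
  cx <- (seq_len(d[1]) - 0.5) * sp
  cy <- (seq_len(d[2]) - 0.5) * sp
  cz <- (seq_len(d[3]) - 0.5) * sp
  CX <- array(rep(cx, times = d[2] * d[3]), d)
  CY <- array(rep(rep(cy, each = d[1]), times = d[3]), d)
  CZ <- array(rep(cz, each = d[1] * d[2]), d)

  ids <- .phantomToothIds(spec$nTeeth)
  pitch <- ext[2] / spec$nTeeth
  jit <- .withSeed(seeds[1], {
    list(dy = stats::runif(spec$nTeeth, -0.05, 0.05) * pitch,
         scale = stats::runif(spec$nTeeth, 0.9, 1.1))
  })
  toothMasks <- list(); crowns <- list()
  zMid <- ext[3] / 2
  crownCentreX <- ext[1] * 0.35
  for (t in seq_len(spec$nTeeth)) {
    yC <- (t - 0.5) * pitch + jit$dy[t]
    s <- jit$scale[t]
    crown <- .superellipsoid(CX, CY, CZ, c(crownCentreX, yC, zMid),
                             spec$crownSemiAxesMm * s, spec$crownExponent)
    rootCentre <- c(crownCentreX + spec$crownSemiAxesMm[1] * s * 0.8 +
                    spec$rootSemiAxesMm[1] * s * 0.5, yC, zMid)
    root <- .superellipsoid(CX, CY, CZ, rootCentre,
                            spec$rootSemiAxesMm * s * c(1, 0.9, 0.9), 2)
    toothMasks[[ids[t]]] <- crown | root
    crowns[[ids[t]]] <- crown
  }

  inten <- spec$intensity
  vol <- array(inten$background, d)
  for (id in ids) {
    vol[toothMasks[[id]]] <- inten$dentin
    vol[crowns[[id]]] <- inten$enamel
  }

  lesionMasks <- list()
  truth <- expand.grid(tooth_fdi = ids, surface = c("mesial", "distal"),
                       stringsAsFactors = FALSE)
  truth$truth <- FALSE; truth$lesionVolumeMm3 <- 0
  if (!is.null(spec$lesions) && nrow(spec$lesions) > 0) {
    for (r in seq_len(nrow(spec$lesions))) {
      id <- as.character(spec$lesions$tooth_fdi[r])
      surf <- spec$lesions$surface[r]
      target <- spec$lesions$targetVolumeMm3[r]
      tm <- toothMasks[[id]]
      toothVol <- sum(tm) * sp^3
      if (target > toothVol)
        stop(sprintf("lesion target %.1f mm^3 exceeds tooth %s volume %.1f mm^3",
                     target, id, toothVol))
      # surface anchor: extreme tooth voxel along the row axis
      vox <- which(tm)
      jIdx <- ((vox - 1L) %/% d[1]) %% d[2] + 1L
      pick <- if (surf == "mesial") vox[jIdx == min(jIdx)] else vox[jIdx == max(jIdx)]
      pick <- pick[ceiling(length(pick) / 2)]
      anchor <- c(CX[pick], CY[pick], CZ[pick])
      lesionOf <- function(rad) .superellipsoid(CX, CY, CZ, anchor, rep(rad, 3), 2) & tm
      lo <- sp; hi <- max(ext)
      for (it in 1:50) {
        mid <- (lo + hi) / 2
        v <- sum(lesionOf(mid)) * sp^3
        if (v < target) lo <- mid else hi <- mid
        if (abs(v - target) <= 0.05 * target) { lo <- hi <- mid; break }
      }
      les <- lesionOf((lo + hi) / 2)
      realised <- sum(les) * sp^3
      if (abs(realised - target) > 0.1 * target)
        stop(sprintf("cannot realise lesion of %.1f mm^3 on tooth %s (got %.1f)",
                     target, id, realised))
      vol[les] <- inten$dentin * (1 - inten$lesionContrast)
      key <- paste(id, surf, sep = ".")
      lesionMasks[[key]] <- BinaryMask(les, sp)
      sel <- truth$tooth_fdi == id & truth$surface == surf
      truth$truth[sel] <- TRUE
      truth$lesionVolumeMm3[sel] <- realised
    }
  }

  if (spec$noiseSigma > 0)
    vol <- vol + .withSeed(seeds[2],
      array(stats::rnorm(prod(d), 0, spec$noiseSigma), d))
  if (spec$streakArtifacts) {
    streaks <- .withSeed(seeds[3], {
      s <- array(0, d)
      for (k in 1:3) {
        j <- sample.int(d[2], 1)
        s[, j, ] <- s[, j, ] + stats::runif(1, 0.3, 0.6) * spec$intensity$enamel
      }
      s
    })
    vol <- vol + streaks
  }

  truth <- cbind(case_id = caseId, truth)
  list(volume = VoxelVolume(vol, sp),
       toothMasks = lapply(toothMasks, BinaryMask, spacing = sp),
       lesionMasks = lesionMasks,
       surfaceTruth = truth)
}

#' Generate a reproducible phantom corpus
#'
#' Fans the master seed out into one child seed per sample; each sample draws
#' lesion presence per surface with probability \code{lesionPrevalence} and a
#' target volume uniform in \code{lesionVolumeRangeMm3}.
#'
#' @param baseSpec template [phantomSpec()] (its \code{lesions} are ignored)
#' @param nSamples number of phantoms
#' @param masterSeed integer master seed
#' @param lesionPrevalence per-surface lesion probability (default 0.3)
#' @param lesionVolumeRangeMm3 uniform range of target volumes (default c(8, 25))
#' @param materialize build the voxel volumes (TRUE) or only the manifest
#' @return list with \code{manifest} (data.frame sample, seed, caseId, nLesions)
#'   and \code{samples} (list of [generatePhantom()] outputs, or of specs when
#'   \code{materialize = FALSE})
#' @export
generateDataset <- function(baseSpec, nSamples, masterSeed = 1L,
                            lesionPrevalence = 0.3,
                            lesionVolumeRangeMm3 = c(8, 25),
                            materialize = TRUE) {
  stopifnot(nSamples >= 1L)
  seeds <- .spawnSeeds(masterSeed, 2L * nSamples)
  geomSeeds <- seeds[seq_len(nSamples)]
  lesSeeds <- seeds[nSamples + seq_len(nSamples)]
  ids <- .phantomToothIds(baseSpec$nTeeth)
  samples <- vector("list", nSamples)
  manifest <- data.frame(sample = seq_len(nSamples), seed = geomSeeds,
                         caseId = sprintf("case%03d", seq_len(nSamples)),
                         nLesions = 0L)
  for (i in seq_len(nSamples)) {
    grid <- expand.grid(tooth_fdi = ids, surface = c("mesial", "distal"),
                        stringsAsFactors = FALSE)
    les <- .withSeed(lesSeeds[i], {
      hit <- stats::runif(nrow(grid)) < lesionPrevalence
      vols <- stats::runif(nrow(grid), lesionVolumeRangeMm3[1],
                           lesionVolumeRangeMm3[2])
      cbind(grid[hit, , drop = FALSE],
            targetVolumeMm3 = vols[hit])
    })
    spec <- baseSpec
    spec$seed <- geomSeeds[i]
    spec$lesions <- if (nrow(les)) les else NULL
    manifest$nLesions[i] <- nrow(les)
    samples[[i]] <- if (materialize)
      generatePhantom(spec, caseId = manifest$caseId[i]) else spec
  }
  list(manifest = manifest, samples = samples)
}

#' Simulate a two-arm reader rating study
#'
#' For every surface in the truth table, each observer makes a binary call
#' (Bernoulli with the model's sensitivity on true lesions, 1 - specificity on
#' sound surfaces) and then draws a five-point confidence score from the
#' call-conditional score distribution.  Deterministic given \code{seed}.
#'
#' @param surfaceTruth data.frame with case_id, tooth_fdi, surface, truth
#' @param observers named list with elements \code{unaided} and \code{aided},
#'   each a named list of [ObserverModel-class] objects (same observer names in
#'   both arms)
#' @param seed integer RNG seed
#' @param repeatCases case ids re-read as session 2 (intra-observer subset)
#' @return a rating table data.frame (see [validateRatingTable()])
#' @export
simulateRatingStudy <- function(surfaceTruth, observers, seed = 1L,
                                repeatCases = NULL) {
  stopifnot(all(c("unaided", "aided") %in% names(observers)))
  obsNames <- names(observers$unaided)
  stopifnot(length(obsNames) >= 1L, setequal(obsNames, names(observers$aided)))
  nS <- nrow(surfaceTruth)
  rows <- list()
  .withSeed(seed, {
    for (arm in c("unaided", "aided")) {
      for (obs in obsNames) {
        mod <- observers[[arm]][[obs]]
        stopifnot(methods::is(mod, "ObserverModel"))
        sessions <- list(`1` = seq_len(nS))
        if (!is.null(repeatCases))
          sessions[["2"]] <- which(surfaceTruth$case_id %in% repeatCases)
        for (ses in names(sessions)) {
          idx <- sessions[[ses]]
          tr <- surfaceTruth$truth[idx]
          pCall <- ifelse(tr, mod@sensitivity, 1 - mod@specificity)
          call <- stats::runif(length(idx)) < pCall
          score <- integer(length(idx))
          nP <- sum(call); nN <- sum(!call)
          if (nP) score[call] <- sample(4:5, nP, TRUE, prob = mod@scorePosCall)
          if (nN) score[!call] <- sample(1:3, nN, TRUE, prob = mod@scoreNegCall)
          rows[[length(rows) + 1L]] <- data.frame(
            case_id = surfaceTruth$case_id[idx],
            tooth_fdi = as.character(surfaceTruth$tooth_fdi[idx]),
            surface = surfaceTruth$surface[idx],
            condition = "intact", observer_id = obs, arm = arm,
            score = score, session = as.integer(ses))
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validateRatingTable(out)
  out
}
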