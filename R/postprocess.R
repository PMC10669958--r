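# Lesion post-processing: connected components, physical volume filtering,
# Youden-anchored probability recalibration, restriction to the dilated tooth.

.connOffsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  l1 <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = l1 == 1, "18" = l1 <= 2, "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  as.matrix(g[keep, , drop = FALSE])
}

# linear indices of valid (src, dst) voxel pairs for one shift
.shiftPairs <- function(d, off) {
  rng <- function(n, o) {
    lo <- max(1L, 1L - o); hi <- min(n, n - o)
    if (hi < lo) integer(0) else lo:hi
  }
  i <- rng(d[1], off[1]); j <- rng(d[2], off[2]); k <- rng(d[3], off[3])
  # src at (i,j,k), dst at (i+o1, j+o2, k+o3); build linear indices vectorised
  li <- function(i, j, k)
    outer(outer(i, (j - 1L) * d[1], "+"), (k - 1L) * d[1] * d[2], "+")
  list(src = as.vector(li(i, j, k)),
       dst = as.vector(li(i + off[1], j + off[2], k + off[3])))
}

#' Label connected lesion components
#'
#' Maximal connected sets of true voxels under the chosen voxel connectivity
#' (6 = faces, 18 = faces+edges, 26 = full neighbourhood).  Labels are dense
#' from 1 in order of each component's first voxel in array (column-major)
#' order, so the labelling is deterministic.
#'
#' @param mask a [BinaryMask-class]
#' @param connectivity 6, 18 or 26 (default 26)
#' @return list with \code{components}, a data.frame with one row per component
#'   (componentId, voxelCount, volumeMm3, and 0-based half-open bbox columns
#'   bbox1Start..bbox3End), and \code{labels}, an integer array (0 = background)
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  stopifnot(methods::is(mask, "BinaryMask"))
  d <- dim(mask@data)
  m <- as.vector(mask@data)
  nTrue <- sum(m)
  labels <- array(0L, d)
  emptyDf <- data.frame(componentId = integer(), voxelCount = integer(),
                        volumeMm3 = numeric(), bbox1Start = integer(),
                        bbox1End = integer(), bbox2Start = integer(),
                        bbox2End = integer(), bbox3Start = integer(),
                        bbox3End = integer())
  if (nTrue == 0L) return(list(components = emptyDf, labels = labels))
  nodeOf <- cumsum(m)                 # voxel linear index -> node id (true voxels)
  offs <- .connOffsets(connectivity)
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    p <- .shiftPairs(d, offs[r, ])
    keep <- m[p$src] & m[p$dst]
    edges[[r]] <- cbind(nodeOf[p$src[keep]], nodeOf[p$dst[keep]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = nTrue, directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  # relabel by first occurrence so labels are dense and deterministic
  first <- match(unique(memb), memb)
  relab <- integer(max(memb)); relab[memb[first]] <- seq_along(first)
  memb <- relab[memb]
  labels[m] <- memb
  vox <- which(m)
  i0 <- (vox - 1L) %% d[1]; j0 <- ((vox - 1L) %/% d[1]) %% d[2]
  k0 <- (vox - 1L) %/% (d[1] * d[2])
  voxelVol <- prod(mask@spacing)
  cnt <- tabulate(memb)
  comps <- data.frame(
    componentId = seq_along(cnt), voxelCount = cnt,
    volumeMm3 = cnt * voxelVol,
    bbox1Start = as.integer(tapply(i0, memb, min)),
    bbox1End = as.integer(tapply(i0, memb, max)) + 1L,
    bbox2Start = as.integer(tapply(j0, memb, min)),
    bbox2End = as.integer(tapply(j0, memb, max)) + 1L,
    bbox3Start = as.integer(tapply(k0, memb, min)),
    bbox3End = as.integer(tapply(k0, memb, max)) + 1L)
  rownames(comps) <- NULL
  list(components = comps, labels = labels)
}

#' Filter lesion components by physical volume
#'
#' A component is kept iff its volume is at least \code{minVolumeCm3 * 1000}
#' mm^3; strictly smaller lesions are ignored, so a lesion exactly at the
#' threshold survives.
#'
#' @param components the data.frame from [labelComponents()]
#' @param minVolumeCm3 minimum lesion volume in cm^3 (default 0.3)
#' @return the retained rows of \code{components}
#' @export
filterByVolume <- function(components, minVolumeCm3 = 0.3) {
  stopifnot(is.data.frame(components), minVolumeCm3 >= 0)
  components[components$volumeMm3 >= minVolumeCm3 * 1000, , drop = FALSE]
}

#' Calibrate the operating threshold (Youden anchor)
#'
#' Finds the threshold t* maximising sensitivity + specificity over candidate
#' cuts placed at midpoints between sorted distinct predicted probabilities
#' (a call is positive when probability > t).  Ties are broken toward the
#' lower threshold.  t* anchors [rescaleProbability()] so that t* maps to 0.5.
#'
#' @param predProbs numeric vector of tooth-level probabilities in [0,1]
#' @param labels binary ground-truth vector (0/1 or logical), both classes present
#' @return a [CalibrationMap-class]
#' @export
calibrateThreshold <- function(predProbs, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(predProbs) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2L)
    stop("calibration requires both classes in labels")
  if (any(predProbs < 0 | predProbs > 1)) stop("probabilities must lie in [0,1]")
  s <- sort(unique(predProbs))
  cand <- if (length(s) >= 2L) (s[-1] + s[-length(s)]) / 2 else (s + 0.5) / 2
  cand <- cand[cand > 0 & cand < 1]
  if (!length(cand)) cand <- 0.5
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  youden <- vapply(cand, function(t) {
    sens <- sum(predProbs > t & labels == 1L) / nPos
    spec <- sum(predProbs <= t & labels == 0L) / nNeg
    sens + spec
  }, numeric(1))
  tStar <- cand[which.max(youden)]   # which.max returns the first (lowest) maximiser
  methods::new("CalibrationMap", tStar = tStar)
}

#' Recalibrate a probability so that t* maps to 0.5
#'
#' The minimal monotone map satisfying the anchoring constraint: piecewise
#' linear with fixed points 0 -> 0, t* -> 0.5, 1 -> 1; strictly increasing and
#' bijective on [0,1] for every t* in (0,1).
#'
#' @param p probability (vectorised), all values in [0,1]
#' @param cal a [CalibrationMap-class]
#' @return recalibrated probabilities, same shape as \code{p}
#' @export
rescaleProbability <- function(p, cal) {
  stopifnot(methods::is(cal, "CalibrationMap"))
  if (any(p < 0 | p > 1, na.rm = FALSE) || anyNA(p))
    stop("probabilities must lie in [0,1]")
  t <- cal@tStar
  out <- ifelse(p <= t, 0.5 * p / t, 0.5 + 0.5 * (p - t) / (1 - t))
  if (is.array(p)) out <- array(out, dim(p))
  out
}

#' Binary dilation of a mask
#'
#' Dilation by a radius-r ball under the chosen connectivity metric,
#' implemented as r iterations of the one-step neighbourhood shift-OR.
#'
#' @param mask a [BinaryMask-class]
#' @param radiusVoxels nonnegative integer dilation radius
#' @param connectivity 6, 18 or 26 (default 26)
#' @return the dilated [BinaryMask-class]
#' @export
dilateMask <- function(mask, radiusVoxels = 1L, connectivity = 26L) {
  stopifnot(methods::is(mask, "BinaryMask"), radiusVoxels >= 0)
  d <- dim(mask@data)
  m <- as.vector(mask@data)
  offs <- .connOffsets(connectivity)
  pairs <- lapply(seq_len(nrow(offs)), function(r) .shiftPairs(d, offs[r, ]))
  for (it in seq_len(radiusVoxels)) {
    grown <- m
    for (p in pairs) grown[p$dst] <- grown[p$dst] | m[p$src]
    m <- grown
  }
  BinaryMask(array(m, d), mask@spacing, mask@origin)
}

#' Restrict lesion predictions to the tooth of interest
#'
#' Multiplies the lesion mask with the binary dilation of the tooth mask,
#' removing predictions situated inside neighbouring teeth.
#'
#' @param lesionMask,toothMask geometry-matched [BinaryMask-class] objects
#' @param dilationRadiusVoxels tooth dilation radius (default 1)
#' @param connectivity structuring-element connectivity (default 26)
#' @return the intersected [BinaryMask-class]
#' @export
intersectWithTooth <- function(lesionMask, toothMask, dilationRadiusVoxels = 1L,
                               connectivity = 26L) {
  .assertGeometryMatch(lesionMask, toothMask, "lesion and tooth masks")
  dil <- dilateMask(toothMask, dilationRadiusVoxels, connectivity)
  BinaryMask(lesionMask@data & dil@data, lesionMask@spacing, lesionMask@origin)
}

#' Full lesion post-processing
#'
#' Converts a raw [CariesPrediction-class] into the final per-tooth call:
#' voxel probabilities are recalibrated and thresholded, restricted to the
#' dilated tooth mask, labelled by connected components, and components below
#' the physical volume threshold are discarded.  The tooth-level probability
#' is recalibrated with the same map.  The final mask is always a subset of
#' the dilated tooth mask, every surviving component meets the volume
#' threshold, and the operation is idempotent on its own output.
#'
#' @param pred a [CariesPrediction-class]
#' @param toothMask the tooth [BinaryMask-class] in network space
#' @param config a [PipelineConfig-class]
#' @param cal a [CalibrationMap-class] (identity anchor 0.5 by default)
#' @param probCutoff voxel cutoff on the recalibrated scale; defaults to
#'   \code{config@probCutoff}
#' @return list with \code{lesionMask} (final [BinaryMask-class]),
#'   \code{components} (retained components data.frame) and \code{toothProb}
#'   (recalibrated scalar probability)
#' @export
runPostprocess <- function(pred, toothMask, config = pipelineConfig(),
                           cal = methods::new("CalibrationMap", tStar = 0.5),
                           probCutoff = config@probCutoff) {
  stopifnot(methods::is(pred, "CariesPrediction"), methods::is(toothMask, "BinaryMask"))
  if (!all(dim(pred@lesionProb) == dim(toothMask@data)))
    stop("prediction and tooth mask have mismatching grid shapes")
  rescaled <- rescaleProbability(pred@lesionProb, cal)
  rawMask <- BinaryMask(rescaled >= probCutoff, toothMask@spacing, toothMask@origin)
  inTooth <- intersectWithTooth(rawMask, toothMask, config@dilationRadiusVoxels,
                                config@connectivity)
  lab <- labelComponents(inTooth, config@connectivity)
  kept <- filterByVolume(lab$components, config@minLesionVolumeCm3)
  finalArr <- array(lab$labels %in% kept$componentId, dim(lab$labels))
  list(lesionMask = BinaryMask(finalArr, toothMask@spacing, toothMask@origin),
       components = kept,
       toothProb = rescaleProbability(pred@toothProb, cal))
}
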