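#' @include AllGenerics.R
NULL

# Central S4 data model.
#
# Axis convention used throughout the package: array axes are, in order,
# (axial, coronal, sagittal); voxel indices are 0-based and voxel ranges are
# half-open [start, end) wherever they appear in exported objects (CropTransform,
# bounding boxes).  Inside R code 1-based subscripts are used and converted at
# the object boundary.

.FDI_CODES <- as.character(c(11:18, 21:28, 31:38, 41:48))
.TOOTH_CONDITIONS <- c("intact", "missing", "restorated", "support", "excluded")

#' VoxelVolume: a 3D scalar grid with physical geometry
#'
#' The common currency of the imaging half of the pipeline: a dense 3D array of
#' intensities together with per-axis voxel spacing (mm) and an origin (mm).
#' CBCT grey values are not Hounsfield-calibrated; intensities are stored as
#' floating point and treated as arbitrary units.
#'
#' @slot data 3D numeric array of intensities
#' @slot spacing numeric length-3, mm per voxel along each axis (all > 0)
#' @slot origin numeric length-3, mm position of the first voxel's corner
#'
#' @seealso [VoxelVolume()], [BinaryMask-class], [readVolume()]
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (any(dim(object@data) < 1L))
    msg <- c(msg, "all three extents must be positive")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a boolean 3D grid sharing VoxelVolume geometry
#'
#' Used for tooth segmentation masks and lesion masks.  The data array is
#' strictly logical; geometry (spacing, origin) follows the same contract as
#' [VoxelVolume-class] so a mask can be paired voxel-for-voxel with a volume.
#'
#' @slot data 3D logical array
#' @slot spacing,origin as in [VoxelVolume-class]
#'
#' @seealso [BinaryMask()], [labelComponents()], [dilateMask()]
#' @export
setClass("BinaryMask", contains = "VoxelVolume")

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@data)) return("mask data must be a logical array")
  if (anyNA(object@data)) return("mask data must not contain NA")
  TRUE
})

#' ToothEntry: one tooth of a case
#'
#' Couples an FDI tooth code with its segmentation mask and the recorded tooth
#' condition.  Valid conditions are intact, missing, restorated, support and
#' excluded; valid FDI codes are 11-18, 21-28, 31-38 and 41-48.
#'
#' @slot toothId character, two-digit FDI code
#' @slot mask a [BinaryMask-class]
#' @slot condition character, one of the five condition labels
#' @export
setClass("ToothEntry",
  representation(toothId = "character", mask = "BinaryMask", condition = "character"),
  prototype(toothId = "11", condition = "intact")
)

setValidity("ToothEntry", function(object) {
  msg <- character()
  if (length(object@toothId) != 1L || !(object@toothId %in% .FDI_CODES))
    msg <- c(msg, sprintf("toothId '%s' is not a valid FDI code", object@toothId))
  if (length(object@condition) != 1L || !(object@condition %in% .TOOTH_CONDITIONS))
    msg <- c(msg, sprintf("condition must be one of: %s",
                          paste(.TOOTH_CONDITIONS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PipelineConfig: geometry and post-processing parameters
#'
#' @slot marginMm mm added on each side of the tooth bounding box (default 3)
#' @slot targetSpacingMm isotropic voxel size of the network input, mm (default 0.25)
#' @slot inputShape fixed network input shape (default 96 x 64 x 64)
#' @slot minLesionVolumeCm3 lesions smaller than this are discarded, cm^3
#'   (default 0.3; see the vignette for a discussion of this value)
#' @slot dilationRadiusVoxels tooth-mask dilation radius used when intersecting
#'   lesion predictions with the tooth of interest (default 1)
#' @slot connectivity voxel connectivity for component labelling: 6, 18 or 26
#' @slot probCutoff voxel probability cutoff forming the binary lesion mask,
#'   applied on the recalibrated scale (default 0.5)
#' @slot resizeMode how the fixed input shape is reached: "interpolate" or
#'   "pad_crop"
#' @export
setClass("PipelineConfig",
  representation(marginMm = "numeric", targetSpacingMm = "numeric",
                 inputShape = "integer", minLesionVolumeCm3 = "numeric",
                 dilationRadiusVoxels = "integer", connectivity = "integer",
                 probCutoff = "numeric", resizeMode = "character"),
  prototype(marginMm = 3, targetSpacingMm = 0.25, inputShape = c(96L, 64L, 64L),
            minLesionVolumeCm3 = 0.3, dilationRadiusVoxels = 1L,
            connectivity = 26L, probCutoff = 0.5, resizeMode = "interpolate")
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@marginMm < 0) msg <- c(msg, "marginMm must be >= 0")
  if (object@targetSpacingMm <= 0) msg <- c(msg, "targetSpacingMm must be > 0")
  if (length(object@inputShape) != 3L || any(object@inputShape < 1L))
    msg <- c(msg, "inputShape must be 3 positive integers")
  if (object@minLesionVolumeCm3 < 0) msg <- c(msg, "minLesionVolumeCm3 must be >= 0")
  if (object@dilationRadiusVoxels < 0L) msg <- c(msg, "dilationRadiusVoxels must be >= 0")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  if (object@probCutoff < 0 || object@probCutoff > 1)
    msg <- c(msg, "probCutoff must lie in [0,1]")
  if (!object@resizeMode %in% c("interpolate", "pad_crop"))
    msg <- c(msg, "resizeMode must be 'interpolate' or 'pad_crop'")
  if (length(msg)) msg else TRUE
})

#' CropTransform: invertible record of the crop/resample/resize chain
#'
#' Everything needed to map a prediction made in fixed network space back to
#' the original scan geometry: the half-open bounding box in source voxels
#' (0-based), the source spacing and shape, the intermediate isotropic spacing,
#' and the scale record written by [resizeToShape()].
#'
#' @slot bbox integer 3x2 matrix, rows = axes, columns = (start, end), 0-based
#'   half-open voxel intervals in the source grid
#' @slot sourceSpacing numeric length-3, mm
#' @slot sourceShape integer length-3, source grid extents
#' @slot intermediateSpacing numeric scalar, the isotropic spacing used, mm
#' @slot intermediateShape integer length-3, grid shape after isotropic
#'   resampling, before the final resize
#' @slot scaleRecord list written by [resizeToShape()] (per-axis factors or
#'   pad/crop offsets), sufficient to invert the shape change exactly
#' @export
setClass("CropTransform",
  representation(bbox = "matrix", sourceSpacing = "numeric", sourceShape = "integer",
                 intermediateSpacing = "numeric", intermediateShape = "integer",
                 scaleRecord = "list")
)

setValidity("CropTransform", function(object) {
  msg <- character()
  b <- object@bbox
  if (!is.numeric(b) || !all(dim(b) == c(3L, 2L)))
    msg <- c(msg, "bbox must be a 3x2 matrix of (start, end) per axis")
  else {
    if (any(b[, 1] < 0) || any(b[, 2] > object@sourceShape) || any(b[, 2] <= b[, 1]))
      msg <- c(msg, "bbox must be nonempty and lie within sourceShape")
  }
  if (length(object@sourceShape) != 3L || any(object@sourceShape < 1L))
    msg <- c(msg, "sourceShape must be 3 positive integers")
  if (length(msg)) msg else TRUE
})

#' CalibrationMap: the Youden-anchored probability recalibration
#'
#' Holds the operating threshold t* (the maximiser of sensitivity +
#' specificity on a calibration set) that [rescaleProbability()] maps to 0.5.
#'
#' @slot tStar numeric in (0, 1)
#' @seealso [calibrateThreshold()], [rescaleProbability()]
#' @export
setClass("CalibrationMap", representation(tStar = "numeric"), prototype(tStar = 0.5))

setValidity("CalibrationMap", function(object) {
  if (length(object@tStar) != 1L || !is.finite(object@tStar) ||
      object@tStar <= 0 || object@tStar >= 1)
    return("tStar must be a single probability strictly inside (0, 1)")
  TRUE
})

#' NetworkConfig: architecture and training hyper-parameters
#'
#' Describes a 3D attention U-Net small enough to train on one CPU.  Encoder
#' levels are connected by stride-2 3x3x3 convolutions; decoding uses nearest
#' neighbour up-sampling, skip concatenation through additive attention gates,
#' deep supervision by element-wise summation of per-level segmentation maps,
#' leaky ReLU activations and instance normalisation.  Channel width doubles
#' per level starting from \code{baseChannels}.
#'
#' @slot nLevels number of resolution levels (>= 2, default 4)
#' @slot baseChannels channels at the finest level (default 8)
#' @slot leakySlope negative slope of the leaky ReLU (default 0.01)
#' @slot deepSupervision logical, combine per-level segmentation maps (default TRUE)
#' @slot attentionGates logical, gate skip connections (default TRUE)
#' @slot learningRate Adam step size (default 1e-3)
#' @slot batchSize samples per optimisation step (default 2)
#' @slot seed integer RNG seed for weight initialisation
#' @export
setClass("NetworkConfig",
  representation(nLevels = "integer", baseChannels = "integer",
                 leakySlope = "numeric", deepSupervision = "logical",
                 attentionGates = "logical", learningRate = "numeric",
                 batchSize = "integer", seed = "integer"),
  prototype(nLevels = 4L, baseChannels = 8L, leakySlope = 0.01,
            deepSupervision = TRUE, attentionGates = TRUE,
            learningRate = 1e-3, batchSize = 2L, seed = 1L)
)

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (object@nLevels < 2L) msg <- c(msg, "nLevels must be >= 2")
  if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
  if (object@leakySlope < 0 || object@leakySlope >= 1)
    msg <- c(msg, "leakySlope must lie in [0, 1)")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' CariesPrediction: raw network output for one tooth volume
#'
#' @slot lesionProb 3D array of voxel probabilities in [0,1], same shape as the
#'   network input
#' @slot toothProb scalar probability that the tooth is pathological
#' @export
setClass("CariesPrediction",
  representation(lesionProb = "array", toothProb = "numeric")
)

setValidity("CariesPrediction", function(object) {
  msg <- character()
  if (length(dim(object@lesionProb)) != 3L)
    msg <- c(msg, "lesionProb must be a 3D array")
  rng <- range(object@lesionProb)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "lesionProb values must lie in [0,1]")
  if (length(object@toothProb) != 1L || object@toothProb < 0 || object@toothProb > 1)
    msg <- c(msg, "toothProb must be a single probability")
  if (length(msg)) msg else TRUE
})

#' ObserverModel: a simulated reader of tooth surfaces
#'
#' A reader is characterised by binary sensitivity/specificity against the
#' surface truth plus a distribution of five-point confidence scores
#' conditional on the binary call: positive calls draw from scores {4, 5},
#' negative calls from scores {1, 2, 3}.
#'
#' @slot sensitivity,specificity probabilities strictly inside (0, 1)
#' @slot scorePosCall probability vector over scores 4:5 given a positive call
#' @slot scoreNegCall probability vector over scores 1:3 given a negative call
#' @seealso [simulateRatingStudy()]
#' @export
setClass("ObserverModel",
  representation(sensitivity = "numeric", specificity = "numeric",
                 scorePosCall = "numeric", scoreNegCall = "numeric"),
  prototype(sensitivity = 0.85, specificity = 0.95,
            scorePosCall = c(`4` = 0.4, `5` = 0.6),
            scoreNegCall = c(`1` = 0.6, `2` = 0.25, `3` = 0.15))
)

setValidity("ObserverModel", function(object) {
  msg <- character()
  for (nm in c("sensitivity", "specificity")) {
    v <- slot(object, nm)
    if (length(v) != 1L || v <= 0 || v >= 1)
      msg <- c(msg, sprintf("%s must lie strictly inside (0, 1)", nm))
  }
  if (length(object@scorePosCall) != 2L || abs(sum(object@scorePosCall) - 1) > 1e-8 ||
      any(object@scorePosCall < 0))
    msg <- c(msg, "scorePosCall must be a probability vector over scores 4:5")
  if (length(object@scoreNegCall) != 3L || abs(sum(object@scoreNegCall) - 1) > 1e-8 ||
      any(object@scoreNegCall < 0))
    msg <- c(msg, "scoreNegCall must be a probability vector over scores 1:3")
  if (length(msg)) msg else TRUE
})

# ---- constructors ----------------------------------------------------------

#' Create a VoxelVolume
#'
#' @param data 3D numeric array
#' @param spacing numeric length-3 (or scalar, recycled), mm per voxel
#' @param origin numeric length-3, mm; defaults to the zero vector
#' @return a [VoxelVolume-class]
#' @examples
#' v <- VoxelVolume(array(rnorm(8), c(2, 2, 2)), spacing = 0.25)
#' voxelSpacing(v)
#' @export
VoxelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "double"
  methods::new("VoxelVolume", data = data, spacing = as.numeric(spacing),
               origin = as.numeric(origin))
}

#' Create a BinaryMask
#'
#' Numeric input is coerced with \code{!= 0}; any other two-valued coding is
#' rejected so masks stay strictly boolean.
#'
#' @param data 3D logical (or 0/1 numeric) array
#' @inheritParams VoxelVolume
#' @return a [BinaryMask-class]
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!is.logical(data)) {
    u <- unique(as.vector(data))
    if (!all(u %in% c(0, 1)))
      stop("mask data must be logical or strictly 0/1")
    data <- array(data != 0, dim(data))
  }
  methods::new("BinaryMask", data = data, spacing = as.numeric(spacing),
               origin = as.numeric(origin))
}

#' Create a ToothEntry
#'
#' @param toothId FDI two-digit code (11-18, 21-28, 31-38, 41-48)
#' @param mask a [BinaryMask-class]
#' @param condition one of "intact", "missing", "restorated", "support", "excluded"
#' @return a [ToothEntry-class]
#' @export
ToothEntry <- function(toothId, mask, condition = "intact") {
  methods::new("ToothEntry", toothId = as.character(toothId), mask = mask,
               condition = condition)
}

#' Create a PipelineConfig
#'
#' Defaults reproduce the published pipeline geometry: a 3 mm bounding-box
#' margin, 0.25 mm isotropic resampling, a fixed 96 x 64 x 64 network input,
#' and a 0.3 cm^3 minimum lesion volume.
#'
#' @param marginMm,targetSpacingMm,inputShape,minLesionVolumeCm3,dilationRadiusVoxels,connectivity,probCutoff,resizeMode
#'   see [PipelineConfig-class]
#' @return a [PipelineConfig-class]
#' @export
pipelineConfig <- function(marginMm = 3, targetSpacingMm = 0.25,
                           inputShape = c(96L, 64L, 64L),
                           minLesionVolumeCm3 = 0.3, dilationRadiusVoxels = 1L,
                           connectivity = 26L, probCutoff = 0.5,
                           resizeMode = "interpolate") {
  methods::new("PipelineConfig", marginMm = marginMm,
               targetSpacingMm = targetSpacingMm,
               inputShape = as.integer(inputShape),
               minLesionVolumeCm3 = minLesionVolumeCm3,
               dilationRadiusVoxels = as.integer(dilationRadiusVoxels),
               connectivity = as.integer(connectivity), probCutoff = probCutoff,
               resizeMode = resizeMode)
}

#' Create a NetworkConfig
#'
#' @param nLevels,baseChannels,leakySlope,deepSupervision,attentionGates,learningRate,batchSize,seed
#'   see [NetworkConfig-class]
#' @return a [NetworkConfig-class]
#' @export
networkConfig <- function(nLevels = 4L, baseChannels = 8L, leakySlope = 0.01,
                          deepSupervision = TRUE, attentionGates = TRUE,
                          learningRate = 1e-3, batchSize = 2L, seed = 1L) {
  methods::new("NetworkConfig", nLevels = as.integer(nLevels),
               baseChannels = as.integer(baseChannels), leakySlope = leakySlope,
               deepSupervision = deepSupervision, attentionGates = attentionGates,
               learningRate = learningRate, batchSize = as.integer(batchSize),
               seed = as.integer(seed))
}

#' Create an ObserverModel
#'
#' @param sensitivity,specificity binary operating characteristics in (0, 1)
#' @param scorePosCall,scoreNegCall confidence-score distributions given the
#'   binary call; see [ObserverModel-class]
#' @return an [ObserverModel-class]
#' @export
observerModel <- function(sensitivity = 0.85, specificity = 0.95,
                          scorePosCall = c(0.4, 0.6),
                          scoreNegCall = c(0.6, 0.25, 0.15)) {
  methods::new("ObserverModel", sensitivity = sensitivity,
               specificity = specificity, scorePosCall = scorePosCall,
               scoreNegCall = scoreNegCall)
}

# ---- accessors & show ------------------------------------------------------

#' @rdname voxelData
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@data)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "VoxelVolume", function(x) x@spacing)

#' @rdname voxelOrigin
#' @export
setMethod("voxelOrigin", "VoxelVolume", function(x) x@origin)

#' @rdname gridShape
#' @export
setMethod("gridShape", "VoxelVolume", function(x) dim(x@data))

#' Threshold probability on a CalibrationMap
#' @param x a [CalibrationMap-class]
#' @return numeric scalar t*
#' @export
tStar <- function(x) {
  stopifnot(methods::is(x, "CalibrationMap"))
  x@tStar
}

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %d x %d x %d, spacing %s mm, origin (%s) mm\n",
              class(object), d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x "),
              paste(format(object@origin, digits = 4), collapse = ", ")))
  if (is.logical(object@data))
    cat(sprintf("  %d foreground voxels (%.2f mm^3)\n", sum(object@data),
                sum(object@data) * prod(object@spacing)))
  else
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(object@data), max(object@data)))
})

setMethod("show", "ToothEntry", function(object) {
  cat(sprintf("ToothEntry FDI %s (%s), mask %s voxels\n", object@toothId,
              object@condition, sum(object@mask@data)))
})

setMethod("show", "CropTransform", function(object) {
  b <- object@bbox
  cat(sprintf("CropTransform: bbox [%d,%d)x[%d,%d)x[%d,%d) of %s, %.3g mm iso\n",
              b[1, 1], b[1, 2], b[2, 1], b[2, 2], b[3, 1], b[3, 2],
              paste(object@sourceShape, collapse = "x"),
              object@intermediateSpacing))
})

setMethod("show", "CalibrationMap", function(object) {
  cat(sprintf("CalibrationMap: t* = %.4f (mapped to probability 0.5)\n", object@tStar))
})

setMethod("show", "CariesPrediction", function(object) {
  cat(sprintf("CariesPrediction: %s voxel grid, tooth probability %.3f\n",
              paste(dim(object@lesionProb), collapse = "x"), object@toothProb))
})

#' Physical volume of a mask in cubic millimetres
#'
#' @param mask a [BinaryMask-class]
#' @return voxel count times the voxel volume, mm^3
#' @export
maskVolumeMm3 <- function(mask) {
  stopifnot(methods::is(mask, "BinaryMask"))
  sum(mask@data) * prod(mask@spacing)
}
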