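# Per-tooth sub-volume extraction and its exact inverse.
#
# Order of operations: crop (tight tooth bbox + margin, clipped to the scan)
# -> isotropic resample (trilinear for intensities, nearest for masks)
# -> resize to the fixed network input shape.  The CropTransform records each
# step so a prediction in network space can be mapped back onto the original
# scan grid.

#' Tooth bounding box with a physical margin
#'
#' The tight bounding box of the true voxels, expanded by
#' \code{round(marginMm / spacing)} voxels per side per axis (rounding to the
#' nearest voxel treats anisotropic sources symmetrically) and clipped to the
#' grid.  Disconnected masks (e.g. multi-rooted teeth split by resampling) use
#' the bounding box of the union of all components.
#'
#' @param mask a nonempty [BinaryMask-class]
#' @param marginMm margin added on each side, mm (default 3)
#' @return integer 3x2 matrix of half-open voxel intervals, 0-based, rows =
#'   axes, columns = (start, end)
#' @export
toothBoundingBox <- function(mask, marginMm = 3) {
  stopifnot(methods::is(mask, "BinaryMask"))
  if (!any(mask@data)) stop("no tooth voxels: the mask is empty")
  d <- dim(mask@data)
  idx <- which(mask@data) - 1L
  i <- idx %% d[1]
  j <- (idx %/% d[1]) %% d[2]
  k <- idx %/% (d[1] * d[2])
  lo <- c(min(i), min(j), min(k))
  hi <- c(max(i), max(j), max(k)) + 1L   # half-open
  mv <- as.integer(round(marginMm / mask@spacing))
  bbox <- cbind(pmax(lo - mv, 0L), pmin(hi + mv, d))
  storage.mode(bbox) <- "integer"
  dimnames(bbox) <- list(NULL, c("start", "end"))
  bbox
}

.cropArray <- function(arr, bbox) {
  arr[(bbox[1, 1] + 1L):bbox[1, 2],
      (bbox[2, 1] + 1L):bbox[2, 2],
      (bbox[3, 1] + 1L):bbox[3, 2], drop = FALSE]
}

#' Extract a tooth sub-volume in fixed network geometry
#'
#' Crops the volume to the tooth bounding box extended by
#' \code{marginMm}, resamples to isotropic \code{targetSpacingMm} voxels and
#' resizes to \code{inputShape}.  The tooth mask is carried through the
#' identical chain with nearest-neighbour interpolation.
#'
#' @param volume the source [VoxelVolume-class]
#' @param tooth a [ToothEntry-class] whose mask geometry matches \code{volume}
#' @param config a [PipelineConfig-class]
#' @return list with \code{toothVolume} (a [VoxelVolume-class] of shape
#'   \code{inputShape}), \code{toothMask} (a [BinaryMask-class], same shape)
#'   and \code{transform} (a [CropTransform-class])
#' @export
extractToothVolume <- function(volume, tooth, config = pipelineConfig()) {
  stopifnot(methods::is(volume, "VoxelVolume"), methods::is(tooth, "ToothEntry"))
  mask <- tooth@mask
  .assertGeometryMatch(volume, mask, "volume and tooth mask")
  bbox <- toothBoundingBox(mask, config@marginMm)

  cropVol <- VoxelVolume(.cropArray(volume@data, bbox), volume@spacing, volume@origin)
  cropMask <- BinaryMask(.cropArray(mask@data, bbox), mask@spacing, mask@origin)

  isoVol <- resampleIsotropic(cropVol, config@targetSpacingMm, "trilinear")
  isoMask <- resampleIsotropic(cropMask, config@targetSpacingMm, "nearest")

  rv <- resizeToShape(isoVol, config@inputShape, config@resizeMode)
  rm_ <- resizeToShape(isoMask, config@inputShape, config@resizeMode)

  transform <- methods::new("CropTransform",
    bbox = bbox, sourceSpacing = volume@spacing,
    sourceShape = as.integer(dim(volume@data)),
    intermediateSpacing = config@targetSpacingMm,
    intermediateShape = as.integer(gridShape(isoVol)),
    scaleRecord = rv$scaleRecord)
  list(toothVolume = rv$volume, toothMask = rm_$volume, transform = transform)
}

#' Map a network-space prediction back to the original scan grid
#'
#' Inverts the resize, resamples from the isotropic grid back to the source
#' spacing (shape forced to the recorded crop shape), and pastes the result
#' into a zero grid of the source shape at the recorded bounding box.  Boolean
#' predictions are restored with nearest-neighbour interpolation and returned
#' as logical; scalar grids use trilinear interpolation.
#'
#' @param prediction 3D array (numeric probabilities or logical mask) with the
#'   network input shape recorded in \code{transform}
#' @param transform the [CropTransform-class] from [extractToothVolume()]
#' @return a 3D array of the original scan shape, zero/FALSE outside the crop
#' @export
restoreToOriginal <- function(prediction, transform) {
  stopifnot(methods::is(transform, "CropTransform"))
  isMask <- is.logical(prediction)
  arr <- prediction
  storage.mode(arr) <- "double"
  rec <- transform@scaleRecord
  if (!all(dim(arr) == rec$targetShape))
    stop(sprintf("prediction shape %s does not match the network input shape %s",
                 paste(dim(arr), collapse = "x"),
                 paste(rec$targetShape, collapse = "x")))
  # 1. undo the fixed-shape resize -> intermediate isotropic grid
  iso <- .invertResize(arr, rec, isMask = isMask)
  if (!all(dim(iso) == transform@intermediateShape))
    stop(sprintf("prediction shape %s does not invert to the recorded grid %s",
                 paste(dim(arr), collapse = "x"),
                 paste(transform@intermediateShape, collapse = "x")))
  # 2. isotropic grid -> crop grid at source spacing
  bbox <- transform@bbox
  cropShape <- as.integer(bbox[, 2] - bbox[, 1])
  crop <- .resampleArray(iso, rep(transform@intermediateSpacing, 3L),
                         cropShape, transform@sourceSpacing,
                         if (isMask) "nearest" else "trilinear")
  # 3. paste into the full-size grid
  out <- array(0, transform@sourceShape)
  out[(bbox[1, 1] + 1L):bbox[1, 2],
      (bbox[2, 1] + 1L):bbox[2, 2],
      (bbox[3, 1] + 1L):bbox[3, 2]] <- crop
  if (isMask) out <- array(out != 0, dim(out))
  out
}

#' Apply a recorded crop transform to another geometry-matched grid
#'
#' Sends any volume or mask living on the source grid through the identical
#' crop -> isotropic resample -> resize chain recorded in \code{transform}
#' (nearest-neighbour for masks, trilinear otherwise).  Forward counterpart of
#' [restoreToOriginal()]; used e.g. to carry lesion ground-truth masks into
#' network space.
#'
#' @param volume a [VoxelVolume-class] or [BinaryMask-class] on the source grid
#' @param transform a [CropTransform-class]
#' @return object of the same class as \code{volume} in network geometry
#' @export
applyCropTransform <- function(volume, transform) {
  stopifnot(methods::is(volume, "VoxelVolume"), methods::is(transform, "CropTransform"))
  if (!all(dim(volume@data) == transform@sourceShape))
    stop("volume shape does not match the transform's source shape")
  isMask <- methods::is(volume, "BinaryMask")
  bbox <- transform@bbox
  cropped <- .cropArray(volume@data, bbox)
  obj <- if (isMask) BinaryMask(cropped, volume@spacing)
         else VoxelVolume(cropped, volume@spacing)
  iso <- resampleIsotropic(obj, transform@intermediateSpacing,
                           if (isMask) "nearest" else "trilinear")
  rec <- transform@scaleRecord
  resizeToShape(iso, rec$targetShape, rec$mode)$volume
}

#' Serialise / read a CropTransform as JSON
#'
#' @param transform a [CropTransform-class]
#' @param path output JSON file
#' @return \code{writeCropTransform}: the path, invisibly;
#'   \code{readCropTransform}: a [CropTransform-class]
#' @export
writeCropTransform <- function(transform, path) {
  x <- list(bbox = transform@bbox, sourceSpacing = transform@sourceSpacing,
            sourceShape = transform@sourceShape,
            intermediateSpacing = transform@intermediateSpacing,
            intermediateShape = transform@intermediateShape,
            scaleRecord = transform@scaleRecord)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeCropTransform
#' @export
readCropTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sr <- x$scaleRecord
  sr$sourceShape <- as.integer(sr$sourceShape)
  methods::new("CropTransform",
    bbox = matrix(as.integer(x$bbox), nrow = 3, byrow = FALSE,
                  dimnames = list(NULL, c("start", "end"))),
    sourceSpacing = as.numeric(x$sourceSpacing),
    sourceShape = as.integer(x$sourceShape),
    intermediateSpacing = as.numeric(x$intermediateSpacing),
    intermediateShape = as.integer(x$intermediateShape),
    scaleRecord = sr)
}
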