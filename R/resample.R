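# 3D grid resampling: trilinear / nearest gather with voxel-centre alignment.
#
# Physical position of voxel index i (0-based) along an axis is
# origin + (i + 0.5) * spacing; all interpolation maps output voxel centres
# into the source grid under that convention and clamps at the borders.

# Interpolate arr at continuous 0-based grid coordinates (xi, yi, zi).
.interp3 <- function(arr, xi, yi, zi, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  if (method == "nearest") {
    ix <- .clamp(round(xi), 0, d[1] - 1)
    iy <- .clamp(round(yi), 0, d[2] - 1)
    iz <- .clamp(round(zi), 0, d[3] - 1)
    return(arr[1L + ix + d[1] * (iy + d[2] * iz)])
  }
  xi <- .clamp(xi, 0, d[1] - 1); yi <- .clamp(yi, 0, d[2] - 1); zi <- .clamp(zi, 0, d[3] - 1)
  x0 <- pmin(floor(xi), d[1] - 1.000001); y0 <- pmin(floor(yi), d[2] - 1.000001)
  z0 <- pmin(floor(zi), d[3] - 1.000001)
  x0 <- floor(.clamp(x0, 0, max(d[1] - 2, 0)))
  y0 <- floor(.clamp(y0, 0, max(d[2] - 2, 0)))
  z0 <- floor(.clamp(z0, 0, max(d[3] - 2, 0)))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  at <- function(ix, iy, iz) arr[1L + ix + d[1] * (iy + d[2] * iz)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
              fy       * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
  fz       * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
              fy       * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
}

# Resample a raw array from srcSpacing to an explicit output shape/spacing.
.resampleArray <- function(arr, srcSpacing, outShape, outSpacing, method) {
  cx <- (seq_len(outShape[1]) - 0.5) * outSpacing[1] / srcSpacing[1] - 0.5
  cy <- (seq_len(outShape[2]) - 0.5) * outSpacing[2] / srcSpacing[2] - 0.5
  cz <- (seq_len(outShape[3]) - 0.5) * outSpacing[3] / srcSpacing[3] - 0.5
  xi <- rep(cx, times = outShape[2] * outShape[3])
  yi <- rep(rep(cy, each = outShape[1]), times = outShape[3])
  zi <- rep(cz, each = outShape[1] * outShape[2])
  array(.interp3(arr, xi, yi, zi, method), outShape)
}

#' Resample a volume to isotropic voxels
#'
#' Output extents are \code{round(extent * spacing / target)} per axis (minimum
#' 1 voxel) so the physical extent is preserved to within one voxel per axis.
#' Binary masks must use (and [BinaryMask-class] inputs automatically use)
#' nearest-neighbour interpolation so the result stays strictly binary.
#'
#' @param volume a [VoxelVolume-class] or [BinaryMask-class]
#' @param targetSpacingMm desired isotropic voxel size, mm (> 0)
#' @param interpolation "trilinear" or "nearest"; masks force "nearest"
#' @return an object of the same class as \code{volume} with spacing
#'   \code{c(t, t, t)}
#' @examples
#' v <- VoxelVolume(array(rnorm(64^3), c(64, 64, 64)), spacing = 0.5)
#' gridShape(resampleIsotropic(v, 0.25))   # 128 128 128
#' @export
resampleIsotropic <- function(volume, targetSpacingMm,
                              interpolation = c("trilinear", "nearest")) {
  if (!is.numeric(targetSpacingMm) || length(targetSpacingMm) != 1L ||
      !is.finite(targetSpacingMm) || targetSpacingMm <= 0)
    stop("targetSpacingMm must be a single positive number")
  interpolation <- match.arg(interpolation)
  isMask <- methods::is(volume, "BinaryMask")
  if (isMask) interpolation <- "nearest"
  d <- dim(volume@data)
  outShape <- pmax(1L, as.integer(round(d * volume@spacing / targetSpacingMm)))
  outSpacing <- rep(targetSpacingMm, 3L)
  arr <- volume@data
  storage.mode(arr) <- "double"
  out <- .resampleArray(arr, volume@spacing, outShape, outSpacing, interpolation)
  if (isMask)
    BinaryMask(out != 0, outSpacing, volume@origin)
  else
    VoxelVolume(out, outSpacing, volume@origin)
}

#' Resize a volume to a fixed grid shape
#'
#' Two modes: \code{"interpolate"} stretches the grid (trilinear for volumes,
#' nearest for masks) so the physical extent is preserved and spacing changes;
#' \code{"pad_crop"} keeps spacing and symmetrically zero-pads or centre-crops
#' each axis.  The returned \code{scaleRecord} contains everything needed to
#' invert the shape change exactly (per-axis source extents and, for pad_crop,
#' the centred offsets).
#'
#' @param volume a [VoxelVolume-class] or [BinaryMask-class]
#' @param targetShape integer length-3, positive extents
#' @param mode "interpolate" (default) or "pad_crop"
#' @return list with elements \code{volume} (resized, same class as input) and
#'   \code{scaleRecord}
#' @export
resizeToShape <- function(volume, targetShape, mode = c("interpolate", "pad_crop")) {
  mode <- match.arg(mode)
  targetShape <- as.integer(targetShape)
  if (length(targetShape) != 3L || any(targetShape < 1L))
    stop("targetShape must be 3 positive integers")
  d <- dim(volume@data)
  isMask <- methods::is(volume, "BinaryMask")
  arr <- volume@data
  storage.mode(arr) <- "double"
  if (mode == "interpolate") {
    outSpacing <- volume@spacing * d / targetShape
    out <- .resampleArray(arr, volume@spacing, targetShape, outSpacing,
                          if (isMask) "nearest" else "trilinear")
    rec <- list(mode = "interpolate", sourceShape = d, targetShape = targetShape,
                factors = d / targetShape, sourceSpacing = volume@spacing)
  } else {
    # centred pad (with zeros/FALSE) or crop per axis; offsets recorded 0-based
    out <- array(0, targetShape)
    diffs <- targetShape - d
    srcLo <- ifelse(diffs < 0, floor(-diffs / 2), 0)       # crop start in source
    dstLo <- ifelse(diffs > 0, floor(diffs / 2), 0)        # pad start in target
    n <- pmin(d, targetShape)
    out[dstLo[1] + seq_len(n[1]), dstLo[2] + seq_len(n[2]), dstLo[3] + seq_len(n[3])] <-
      arr[srcLo[1] + seq_len(n[1]), srcLo[2] + seq_len(n[2]), srcLo[3] + seq_len(n[3])]
    outSpacing <- volume@spacing
    rec <- list(mode = "pad_crop", sourceShape = d, targetShape = targetShape,
                srcLo = srcLo, dstLo = dstLo, sourceSpacing = volume@spacing)
  }
  vol <- if (isMask) BinaryMask(out != 0, outSpacing, volume@origin)
         else VoxelVolume(out, outSpacing, volume@origin)
  list(volume = vol, scaleRecord = rec)
}

# Invert resizeToShape on a raw array (values interpolated back onto the
# original grid; nearest for masks).
.invertResize <- function(arr, scaleRecord, isMask = FALSE) {
  rec <- scaleRecord
  d <- dim(arr)
  src <- as.integer(rec$sourceShape)
  if (rec$mode == "interpolate") {
    # arr lives on the resized grid; map source-grid voxel centres back into it
    # (relative coordinates: one arr voxel = 1 unit, one source voxel = d/src)
    .resampleArray(arr, c(1, 1, 1), src, d / src,
                   if (isMask) "nearest" else "trilinear")
  } else {
    out <- array(0, src)
    n <- pmin(d, src)
    srcLo <- rec$srcLo; dstLo <- rec$dstLo
    out[srcLo[1] + seq_len(n[1]), srcLo[2] + seq_len(n[2]), srcLo[3] + seq_len(n[3])] <-
      arr[dstLo[1] + seq_len(n[1]), dstLo[2] + seq_len(n[2]), dstLo[3] + seq_len(n[3])]
    out
  }
}
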