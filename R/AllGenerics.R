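#' Access the voxel data array
#'
#' @param x a [VoxelVolume-class] or [BinaryMask-class]
#' @return the underlying 3D array (numeric for volumes, logical for masks)
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Access the voxel spacing in millimetres
#'
#' @param x a [VoxelVolume-class] or [BinaryMask-class]
#' @return numeric length-3 vector, mm per voxel along each axis
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Access the volume origin in millimetres
#'
#' @param x a [VoxelVolume-class] or [BinaryMask-class]
#' @return numeric length-3 vector
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' Grid shape (voxel extents) of a volume or mask
#'
#' @param x a [VoxelVolume-class] or [BinaryMask-class]
#' @return integer length-3 vector of extents
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
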