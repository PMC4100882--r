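## Constructors and accessors for grid-borne objects.

#' Construct a CT intensity volume
#'
#' @param hu 3D numeric array of intensities in Hounsfield units.
#' @param spacing numeric(3), voxel spacing in mm.
#' @param origin numeric(3), physical position (mm) of the centre of the
#'   first voxel.
#' @return A [VoxelVolume-class].
#' @examples
#' v <- VoxelVolume(array(-1000, c(4, 4, 4)), spacing = c(1, 1, 2))
#' voxelSpacing(v)
#' @export
VoxelVolume <- function(hu, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(hu) || length(dim(hu)) != 3L)
    stop("hu must be a 3D array")
  storage.mode(hu) <- "double"
  new("VoxelVolume", hu = hu, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a voxel-aligned mask
#'
#' When `template` is given (a [VoxelVolume-class] or another mask) the grid
#' metadata is inherited and a shape mismatch against the template is an
#' error, enforcing the shared-grid contract.
#'
#' @param bits 3D logical array (binary mask) or non-negative integer array
#'   (label map).
#' @param template optional parent [VoxelGrid-class] object supplying
#'   spacing/origin; shapes must agree.
#' @param spacing,origin grid metadata, used when no template is given.
#' @return A [BinaryMask-class].
#' @export
BinaryMask <- function(bits, template = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  if (!is.array(bits) || length(dim(bits)) != 3L)
    stop("bits must be a 3D array")
  if (is.double(bits)) storage.mode(bits) <- "integer"
  if (!is.null(template)) {
    if (!is(template, "VoxelGrid"))
      stop("template must be a VoxelVolume or BinaryMask")
    if (!identical(dim(bits), gridDim(template)))
      stop("mask shape does not match its parent volume's grid")
    spacing <- voxelSpacing(template)
    origin <- voxelOrigin(template)
  }
  new("BinaryMask", bits = bits, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn VoxelVolume the intensity array (HU).
#' @param x a grid-borne object.
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@hu)

#' @describeIn BinaryMask the mask array.
#' @param x a grid-borne object.
#' @export
setMethod("voxelData", "BinaryMask", function(x) x@bits)

#' @describeIn VoxelVolume voxel spacing in mm.
#' @export
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)

#' @describeIn VoxelVolume physical origin in mm.
#' @export
setMethod("voxelOrigin", "VoxelGrid", function(x) x@origin)

#' Grid dimensions of a volume or mask
#'
#' @param x a [VoxelVolume-class], [BinaryMask-class] or [FragmentSet-class].
#' @return integer(3) grid dimensions.
#' @export
gridDim <- function(x) {
  if (is(x, "VoxelVolume")) dim(x@hu)
  else if (is(x, "BinaryMask")) dim(x@bits)
  else if (is(x, "FragmentSet")) dim(x@labels)
  else stop("not a grid object")
}

## logical foreground of a mask (labels > 0 for label maps)
.maskBits <- function(mask) {
  b <- voxelData(mask)
  if (is.logical(b)) b else b > 0L
}

## physical coordinate of 1-based voxel indices (n x 3 matrix or vector)
.voxelToMm <- function(idx, grid) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, voxelSpacing(grid), "*"), 2, voxelOrigin(grid), "+")
}

## bounding box (1-based index ranges) of TRUE voxels, padded by `pad`
## voxels and clipped to the grid; NULL for an empty mask
.maskBBox <- function(bits, pad = 1L) {
  d <- dim(bits)
  xs <- which(rowSums(matrix(bits, nrow = d[1])) > 0)
  if (!length(xs)) return(NULL)
  yz <- colSums(matrix(bits, nrow = d[1])) # sums per (y, z) column
  ys <- which(rowSums(matrix(yz, nrow = d[2])) > 0)
  zs <- which(colSums(matrix(bits, ncol = d[3])) > 0)
  list(x = c(max(1L, min(xs) - pad), min(d[1], max(xs) + pad)),
       y = c(max(1L, min(ys) - pad), min(d[2], max(ys) + pad)),
       z = c(max(1L, min(zs) - pad), min(d[3], max(zs) + pad)))
}
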