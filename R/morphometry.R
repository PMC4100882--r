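## Cavity morphometry: volume, cross-sectional area profile, PCA axes and
## deflection angle, and the maximal inscribed sphere (depth of maximal
## damage).

#' Volume of a mask in millilitres
#'
#' Voxel count times voxel volume.
#'
#' @param mask a [BinaryMask-class].
#' @return Volume in mL.
#' @examples
#' m <- BinaryMask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)))
#' maskVolume(m) # 0.001 mL for one 1 mm^3 voxel
#' @export
setMethod("maskVolume", "BinaryMask", function(mask) {
  sum(.maskBits(mask)) * prod(voxelSpacing(mask)) / 1000
})

#' Cross-sectional area profile along the block axis
#'
#' Per-slice foreground area (voxel count times in-plane voxel area) along
#' z, reported against depth in mm. Depth zero is `zRefMm` when given
#' (e.g. the block entry face), otherwise the first slice containing the
#' mask.
#'
#' @param mask a [BinaryMask-class].
#' @param zRefMm physical z (mm) taken as depth zero, or `NULL`.
#' @return data.frame with columns `depth_mm` and `area_mm2`, one row per
#'   slice spanned by the mask.
#' @export
setMethod("areaProfile", "BinaryMask", function(mask, zRefMm = NULL) {
  bits <- .maskBits(mask)
  sp <- voxelSpacing(mask)
  counts <- colSums(matrix(bits, ncol = dim(bits)[3]))
  zidx <- which(counts > 0)
  if (!length(zidx))
    return(data.frame(depth_mm = numeric(0), area_mm2 = numeric(0)))
  zidx <- seq(min(zidx), max(zidx))
  zmm <- voxelOrigin(mask)[3] + (zidx - 1) * sp[3]
  ref <- if (is.null(zRefMm)) zmm[1] else zRefMm
  data.frame(depth_mm = zmm - ref, area_mm2 = counts[zidx] * sp[1] * sp[2])
})

#' Principal axis of a mask
#'
#' Unit eigenvector with the largest eigenvalue of the covariance of the
#' (unweighted) physical voxel coordinates, sign-fixed so the z component
#' is non-negative. When the two leading eigenvalues are close (near
#' isotropic mask, e.g. a sphere) the direction is ill-defined; a warning
#' is raised and the result carries `attr(, "degenerate") = TRUE`.
#'
#' @param mask a [BinaryMask-class] with at least 3 foreground voxels.
#' @param degenerateRatio eigenvalue ratio (largest/second) below which the
#'   axis is flagged degenerate (default 1.5).
#' @return Unit numeric(3) vector.
#' @export
setMethod("principalAxis", "BinaryMask",
  function(mask, degenerateRatio = 1.5) {
    idx <- which(.maskBits(mask), arr.ind = TRUE)
    if (nrow(idx) < 3L) stop("mask too small for a principal axis")
    # covariance is translation invariant: scale indices by spacing only
    storage.mode(idx) <- "double"
    cv <- stats::cov(idx %*% diag(voxelSpacing(mask)))
    eg <- eigen(cv, symmetric = TRUE)
    ax <- eg$vectors[, 1]
    if (ax[3] < 0) ax <- -ax
    degenerate <- eg$values[2] > 0 &&
      eg$values[1] / eg$values[2] < degenerateRatio
    if (degenerate)
      warning(sprintf(
        "principal axis ill-defined: eigenvalue ratio %.2f < %.2f",
        eg$values[1] / max(eg$values[2], .Machine$double.eps),
        degenerateRatio))
    ax <- ax / sqrt(sum(ax^2))
    attr(ax, "degenerate") <- degenerate
    ax
  })

#' Deflection angle between cavity and block
#'
#' Angle between the principal axes of the cavity and of the block, in
#' degrees, folded into [0, 90] via the absolute dot product (eigenvector
#' signs are arbitrary). This measures how far the wound channel deviates
#' from the line of shooting.
#'
#' @param cavityMask,blockMask [BinaryMask-class] objects on the same grid.
#' @return Angle in degrees; carries `attr(, "degenerate")` when either
#'   axis was ill-defined.
#' @examples
#' # identical masks have angle 0
#' @export
setMethod("deflectionAngle", c("BinaryMask", "BinaryMask"),
  function(cavityMask, blockMask) {
    if (!identical(gridDim(cavityMask), gridDim(blockMask)))
      stop("masks are not on the same grid")
    a1 <- principalAxis(cavityMask)
    a2 <- principalAxis(blockMask)
    dt <- min(1, abs(sum(a1 * a2)))
    ang <- acos(dt) * 180 / pi
    attr(ang, "degenerate") <- isTRUE(attr(a1, "degenerate")) ||
      isTRUE(attr(a2, "degenerate"))
    ang
  })

#' Maximal inscribed sphere of a cavity
#'
#' Computes the anisotropic Euclidean distance transform inside the mask
#' (distance in mm from each cavity voxel to the nearest non-cavity voxel;
#' the grid border counts as boundary). The maximum of this distance map is
#' the radius of the maximal fitting sphere and its position the sphere
#' centre; the centre's z quantifies the depth of maximal damage. Ties are
#' broken towards the smallest z, then y, then x.
#'
#' @param mask a non-empty [BinaryMask-class].
#' @param zRefMm physical z (mm) taken as depth zero (e.g. the block entry
#'   face); when `NULL` the reported depth equals the centre's physical z.
#' @return list with `radius_mm`, `center_mm` (numeric(3)) and `depth_mm`.
#' @export
setMethod("maxInscribedSphere", "BinaryMask", function(mask, zRefMm = NULL) {
  bits <- .maskBits(mask)
  if (!any(bits)) stop("empty mask")
  sp <- voxelSpacing(mask)
  # the transform is local: restrict to the cavity bounding box plus one
  # background layer (exact as long as the mask does not touch the border,
  # where the border itself is boundary anyway)
  bb <- .maskBBox(bits, pad = 1L)
  sub <- bits[bb$x[1]:bb$x[2], bb$y[1]:bb$y[2], bb$z[1]:bb$z[2],
              drop = FALSE]
  edt <- cpp_edt(as.logical(sub), dim(sub), sp, TRUE)
  r <- max(edt)
  cand <- which(edt >= r - 1e-12, arr.ind = TRUE)
  cand <- cand[order(cand[, 3], cand[, 2], cand[, 1]), , drop = FALSE]
  idx <- cand[1, ] + c(bb$x[1], bb$y[1], bb$z[1]) - 1L
  ctr <- .voxelToMm(idx, mask)[1, ]
  depth <- if (is.null(zRefMm)) ctr[3] else ctr[3] - zRefMm
  list(radius_mm = r, center_mm = unname(ctr), depth_mm = unname(depth))
})

#' Assemble cavity metrics
#'
#' Convenience constructor combining the individual morphometry operations
#' on a cavity/block mask pair into one [CavityMetrics-class] record.
#'
#' @param cavityMask,blockMask [BinaryMask-class] objects on the same grid.
#' @param entryZMm physical z (mm) of the block entry face, used as depth
#'   zero; defaults to the first slice of the block mask.
#' @return A [CavityMetrics-class].
#' @export
cavityMetrics <- function(cavityMask, blockMask, entryZMm = NULL) {
  if (is.null(entryZMm)) {
    bb <- .maskBits(blockMask)
    zAny <- which(colSums(matrix(bb, ncol = dim(bb)[3])) > 0)
    entryZMm <- voxelOrigin(blockMask)[3] +
      (min(zAny) - 1) * voxelSpacing(blockMask)[3]
  }
  ang <- deflectionAngle(cavityMask, blockMask)
  sph <- maxInscribedSphere(cavityMask, zRefMm = entryZMm)
  new("CavityMetrics",
      volumeMl = maskVolume(cavityMask),
      deflectionDeg = as.numeric(ang),
      sphereRadiusMm = sph$radius_mm,
      sphereCenterMm = sph$center_mm,
      maxDamageDepthMm = sph$depth_mm,
      areaProfile = areaProfile(cavityMask, zRefMm = entryZMm),
      degenerateAxis = isTRUE(attr(ang, "degenerate")))
}
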