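## S4 classes shared across the package.
##
## Grid convention: arrays are indexed [x, y, z] with z the long axis of the
## soap block (the shot direction). Voxel i (1-based) has its centre at
## origin + (i - 1) * spacing (voxel-centre convention), all in mm.

#' Virtual parent for objects living on a voxel grid
#'
#' Carries the grid geometry shared by [VoxelVolume-class] and
#' [BinaryMask-class]: voxel spacing and physical origin, both in mm.
#'
#' @slot spacing numeric(3), voxel spacing in mm (x, y, z); strictly positive.
#' @slot origin numeric(3), physical position (mm) of the centre of voxel
#'   (1, 1, 1).
#' @keywords classes
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation("VIRTUAL", spacing = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  TRUE
})

#' CT intensity volume
#'
#' A 3D grid of CT intensities in Hounsfield units (HU) with voxel spacing
#' and origin metadata. Axis 3 (z) is the long axis of the soap block, i.e.
#' the shot direction.
#'
#' @slot hu 3D numeric array of intensities (HU).
#' @slot spacing,origin see [VoxelGrid-class].
#' @seealso [VoxelVolume()], [readVolume()], [generatePhantom()]
#' @exportClass VoxelVolume
setClass("VoxelVolume", contains = "VoxelGrid", representation(hu = "array"))

setValidity("VoxelVolume", function(object) {
  d <- dim(object@hu)
  if (length(d) != 3L || any(d < 1L)) return("hu must be a non-empty 3D array")
  rng <- range(object@hu)
  if (!all(is.finite(rng))) return("intensities must be finite")
  if (rng[1] < -2048 || rng[2] > 32767)
    return("intensities outside the plausible HU range [-2048, 32767]")
  TRUE
})

#' Voxel-aligned segmentation mask
#'
#' A binary or label mask on the same grid as its parent [VoxelVolume-class].
#' `bits` holds 0/1 for a binary mask or small non-negative integer labels
#' for a label map (e.g. per-fragment labels).
#'
#' @slot bits 3D integer (or logical) array; 0 is background.
#' @slot spacing,origin see [VoxelGrid-class].
#' @seealso [BinaryMask()], [segmentBlock()], [segmentCavity()]
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "VoxelGrid", representation(bits = "array"))

setValidity("BinaryMask", function(object) {
  d <- dim(object@bits)
  if (length(d) != 3L || any(d < 1L))
    return("bits must be a non-empty 3D array")
  if (!is.logical(object@bits) && !is.integer(object@bits))
    return("bits must be logical or integer")
  if (is.integer(object@bits) && any(object@bits < 0L))
    return("labels must be non-negative")
  TRUE
})

#' Parametric description of a synthetic soap-block phantom
#'
#' Full parameterisation of a CT-like soap block: block extents, voxel
#' spacing, rendering intensities, the cavity shape family with its
#' parameters, metal fragments, streak artifacts and acquisition noise.
#' Built with [phantomSpec()], consumed by [generatePhantom()].
#'
#' @slot blockShapeMm numeric(3), block extents in mm (x, y, z; z = shot axis).
#' @slot voxelSpacingMm numeric(3), voxel spacing in mm.
#' @slot soapHu,airHu,fragmentHu rendering intensities (HU); soap must lie
#'   strictly between air and fragment, and fragment strictly above 2000 HU.
#' @slot cavityFamily one of `"tumbling_spindle"`, `"early_opening"`,
#'   `"tear_shaped"`, `"cylinder"`, `"ellipsoid"`.
#' @slot cavityParams named list of family parameters (see [cavityProfile()]).
#' @slot nFragments integer, number of spherical metal fragments.
#' @slot fragmentRadiusRangeMm numeric(2), fragment radius range (mm).
#' @slot streakArtifacts logical, render streak spokes and specks near large
#'   fragments.
#' @slot noiseSdHu numeric, Gaussian noise standard deviation (HU).
#' @slot marginMm numeric, air margin around the block (mm).
#' @slot seed integer, RNG seed; fixes the rendered volume bit-for-bit.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  blockShapeMm = "numeric", voxelSpacingMm = "numeric",
  soapHu = "numeric", airHu = "numeric", fragmentHu = "numeric",
  cavityFamily = "character", cavityParams = "list",
  nFragments = "integer", fragmentRadiusRangeMm = "numeric",
  streakArtifacts = "logical", noiseSdHu = "numeric",
  marginMm = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@blockShapeMm) != 3L || any(object@blockShapeMm <= 0))
    return("blockShapeMm must be 3 positive extents (mm)")
  if (length(object@voxelSpacingMm) != 3L || any(object@voxelSpacingMm <= 0))
    return("voxelSpacingMm must be 3 positive values (mm)")
  if (object@fragmentHu <= 2000)
    return("fragmentHu must be strictly above the 2000 HU fragment threshold")
  if (object@soapHu <= object@airHu || object@soapHu >= object@fragmentHu)
    return("soapHu must lie strictly between airHu and fragmentHu")
  if (!object@cavityFamily %in% .cavityFamilies())
    return(sprintf("unknown cavity family '%s'", object@cavityFamily))
  if (object@nFragments < 0L) return("nFragments must be >= 0")
  if (object@noiseSdHu < 0) return("noiseSdHu must be >= 0")
  if (length(object@fragmentRadiusRangeMm) != 2L ||
      any(object@fragmentRadiusRangeMm <= 0) ||
      diff(object@fragmentRadiusRangeMm) < 0)
    return("fragmentRadiusRangeMm must be an increasing positive pair")
  msg <- .checkCavityFits(object)
  if (!isTRUE(msg)) return(msg)
  TRUE
})

#' Ground truth of a synthetic phantom
#'
#' Analytic ground truth recorded by [generatePhantom()] for recovery
#' testing: cavity volume, axis, tilt, fragment geometry and the maximal
#' inscribed sphere of the parametric cavity.
#'
#' @slot volumeMl analytic cavity volume (mL).
#' @slot axis unit vector of the cavity axis.
#' @slot tiltDeg tilt of the cavity axis against the block long axis (deg).
#' @slot fragmentCentersMm n x 3 matrix of fragment centres (mm).
#' @slot fragmentRadiiMm fragment radii (mm).
#' @slot sphereRadiusMm radius of the maximal inscribed sphere (mm).
#' @slot sphereDepthMm depth (mm along z from the entry face) of its centre.
#' @slot sphereCenterMm centre of the maximal inscribed sphere (mm).
#' @slot entryZMm physical z (mm) of the block entry face.
#' @exportClass PhantomTruth
setClass("PhantomTruth", representation(
  volumeMl = "numeric", axis = "numeric", tiltDeg = "numeric",
  fragmentCentersMm = "matrix", fragmentRadiiMm = "numeric",
  sphereRadiusMm = "numeric", sphereDepthMm = "numeric",
  sphereCenterMm = "numeric", entryZMm = "numeric"))

setValidity("PhantomTruth", function(object) {
  if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    return("axis must have unit norm")
  if (object@volumeMl <= 0) return("volumeMl must be positive")
  TRUE
})

#' Segmented metal fragments
#'
#' Connected components of voxels above the 2000 HU fragment threshold,
#' with per-fragment statistics and a `counted` flag set by the
#' streak-artifact exclusion rule ([applyStreakExclusion()]). Excluded
#' fragments are retained in the table but flagged.
#'
#' @slot table data.frame with columns `label`, `n_voxels`, `volume_mm3`,
#'   `centroid_x_mm`, `centroid_y_mm`, `centroid_z_mm`, `max_hu`, `counted`.
#' @slot labels 3D integer array of fragment labels (0 = background).
#' @slot spacing,origin see [VoxelGrid-class].
#' @seealso [segmentFragments()], [countedFragments()]
#' @exportClass FragmentSet
setClass("FragmentSet", contains = "VoxelGrid",
  representation(table = "data.frame", labels = "array"))

setValidity("FragmentSet", function(object) {
  need <- c("label", "n_voxels", "volume_mm3", "centroid_x_mm",
            "centroid_y_mm", "centroid_z_mm", "max_hu", "counted")
  if (!all(need %in% names(object@table)))
    return("fragment table is missing required columns")
  if (nrow(object@table) > 0 && any(object@table$max_hu <= 2000))
    return("every fragment's max intensity must exceed 2000 HU")
  TRUE
})

#' Morphometric descriptors of a wound cavity
#'
#' The CT-derived descriptors of one cavity: volume, cross-sectional area
#' profile along the shot axis, deflection angle between cavity and block
#' principal axes, and the maximal inscribed sphere whose z-position marks
#' the depth of maximal damage.
#'
#' @slot volumeMl cavity volume (mL).
#' @slot deflectionDeg deflection angle in degrees, folded into [0, 90].
#' @slot sphereRadiusMm radius of the maximal inscribed sphere (mm).
#' @slot sphereCenterMm its centre (mm, physical coordinates).
#' @slot maxDamageDepthMm depth of the sphere centre along z, measured from
#'   the block entry face (mm).
#' @slot areaProfile data.frame with columns `depth_mm`, `area_mm2`.
#' @slot degenerateAxis logical, TRUE when the cavity PCA axis was
#'   ill-defined (near-isotropic mask).
#' @seealso [analyzeShot()]
#' @exportClass CavityMetrics
setClass("CavityMetrics", representation(
  volumeMl = "numeric", deflectionDeg = "numeric",
  sphereRadiusMm = "numeric", sphereCenterMm = "numeric",
  maxDamageDepthMm = "numeric", areaProfile = "data.frame",
  degenerateAxis = "logical"))

setValidity("CavityMetrics", function(object) {
  if (object@deflectionDeg < 0 || object@deflectionDeg > 90)
    return("deflectionDeg must lie in [0, 90]")
  TRUE
})

#' Segment-wise truncated-cone cavity model (cutting method)
#'
#' The legacy cutting-method model: sparse (depth, radius) delineations of
#' the cut-open cavity joined by truncated cones (frusta). Built with
#' [buildConeModel()].
#'
#' @slot knots data.frame with columns `depth_mm` (strictly increasing) and
#'   `radius_mm` (non-negative).
#' @slot segmentVolumesMm3 per-segment frustum volumes (mm^3).
#' @seealso [coneVolume()], [coneAreaProfile()]
#' @exportClass ConeModel
setClass("ConeModel",
  representation(knots = "data.frame", segmentVolumesMm3 = "numeric"))

setValidity("ConeModel", function(object) {
  k <- object@knots
  if (nrow(k) < 2L) return("need at least 2 knots")
  if (any(diff(k$depth_mm) <= 0)) return("depths must be strictly increasing")
  if (any(k$radius_mm < 0)) return("radii must be non-negative")
  TRUE
})

#' Through-origin regression fit
#'
#' Least-squares fit of y on {x} (linear) or {x, x^2} (quadratic) with no
#' intercept, as produced by [fitThroughOrigin()]. R-squared is computed
#' against the grand-mean baseline and can be negative for through-origin
#' fits; AIC uses the least-squares form n*log(RSS/n) + 2k with the error
#' variance counted in k.
#'
#' @slot model `"linear_origin"` or `"quadratic_origin"`.
#' @slot coefficients named coefficients (`x`, and `x2` for quadratic).
#' @slot rss residual sum of squares.
#' @slot rSquared coefficient of determination vs the mean-of-y baseline.
#' @slot aic Akaike information criterion (least-squares form).
#' @slot n number of observations.
#' @exportClass RegressionResult
setClass("RegressionResult", representation(
  model = "character", coefficients = "numeric", rss = "numeric",
  rSquared = "numeric", aic = "numeric", n = "integer"))

setValidity("RegressionResult", function(object) {
  k <- length(object@coefficients)
  if (object@model == "linear_origin" && k != 1L)
    return("linear_origin must have exactly 1 coefficient")
  if (object@model == "quadratic_origin" && k != 2L)
    return("quadratic_origin must have exactly 2 coefficients")
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    return("rSquared cannot exceed 1")
  TRUE
})

## ---- show methods ----

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@hu)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  HU range [%.0f, %.0f], origin (%s) mm\n",
              min(object@hu), max(object@hu),
              paste(format(object@origin, digits = 4), collapse = ", ")))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@bits)
  nl <- if (is.logical(object@bits)) sum(object@bits) else sum(object@bits > 0L)
  cat(sprintf("BinaryMask: %d x %d x %d voxels, %d foreground (%.3f mL)\n",
              d[1], d[2], d[3], nl,
              nl * prod(object@spacing) / 1000))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s cavity in %s mm block, %s mm voxels, seed %d\n",
              object@cavityFamily,
              paste(object@blockShapeMm, collapse = "x"),
              paste(format(object@voxelSpacingMm, digits = 3), collapse = "x"),
              object@seed))
  cat(sprintf("  %d fragments, streaks %s, noise sd %.1f HU\n",
              object@nFragments,
              if (object@streakArtifacts) "on" else "off", object@noiseSdHu))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: volume %.2f mL, tilt %.2f deg, %d fragments\n",
    object@volumeMl, object@tiltDeg, length(object@fragmentRadiiMm)))
  cat(sprintf("  max sphere r = %.2f mm at depth %.1f mm\n",
              object@sphereRadiusMm, object@sphereDepthMm))
})

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet: %d fragments (%d counted)\n",
              nrow(object@table), sum(object@table$counted)))
})

setMethod("show", "CavityMetrics", function(object) {
  cat(sprintf(
    "CavityMetrics: %.2f mL, deflection %.2f deg, max sphere r %.2f mm at depth %.1f mm\n",
    object@volumeMl, object@deflectionDeg, object@sphereRadiusMm,
    object@maxDamageDepthMm))
})

setMethod("show", "ConeModel", function(object) {
  cat(sprintf("ConeModel: %d knots, %d frusta, total volume %.2f mL\n",
              nrow(object@knots), length(object@segmentVolumesMm3),
              sum(object@segmentVolumesMm3) / 1000))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult (%s): n = %d, R^2 = %.4f, AIC = %.2f\n",
              object@model, object@n, object@rSquared, object@aic))
  print(object@coefficients)
})
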