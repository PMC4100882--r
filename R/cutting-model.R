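## The legacy cutting method: a cut-open block is photographed and the
## cavity delineated sparsely as (depth, radius) pairs; between successive
## delineations the cavity is modelled as a truncated cone (frustum).

#' Build a truncated-cone cavity model
#'
#' From ordered (depth, radius) knots, each adjacent pair defines a frustum
#' with volume \eqn{V = \pi h / 3 (r_1^2 + r_1 r_2 + r_2^2)}. Radii are
#' linear in depth between knots (the frustum assumption; no smoothing).
#'
#' @param knots data.frame or matrix with columns `depth_mm` (strictly
#'   increasing) and `radius_mm` (non-negative), or a numeric vector of
#'   depths when `radius` is given separately.
#' @param radius optional numeric vector of radii matching `knots`.
#' @param diameters when TRUE the second column holds diameters and is
#'   halved (delineations are sometimes recorded across the cavity).
#' @return A [ConeModel-class].
#' @examples
#' m <- buildConeModel(data.frame(depth_mm = c(0, 100),
#'                                radius_mm = c(5, 5)))
#' coneVolume(m) # cylinder limit: pi * 25 * 100
#' @export
buildConeModel <- function(knots, radius = NULL, diameters = FALSE) {
  if (!is.null(radius)) {
    knots <- data.frame(depth_mm = as.numeric(knots),
                        radius_mm = as.numeric(radius))
  } else {
    knots <- as.data.frame(knots)
    if (!all(c("depth_mm", "radius_mm") %in% names(knots))) {
      if (ncol(knots) >= 2) names(knots)[1:2] <- c("depth_mm", "radius_mm")
      else stop("knots need columns depth_mm and radius_mm")
    }
  }
  knots <- knots[, c("depth_mm", "radius_mm")]
  if (diameters) knots$radius_mm <- knots$radius_mm / 2
  if (nrow(knots) < 2L) stop("need at least 2 knots")
  if (any(duplicated(knots$depth_mm)) || is.unsorted(knots$depth_mm,
                                                     strictly = TRUE))
    stop("depths must be strictly increasing without duplicates")
  if (any(knots$radius_mm < 0)) stop("radii must be non-negative")
  h <- diff(knots$depth_mm)
  r1 <- head(knots$radius_mm, -1)
  r2 <- tail(knots$radius_mm, -1)
  segs <- pi * h / 3 * (r1^2 + r1 * r2 + r2^2)
  new("ConeModel", knots = knots, segmentVolumesMm3 = segs)
}

#' @describeIn buildConeModel total model volume in mm^3 (sum of frustum
#'   volumes).
#' @param model a [ConeModel-class].
#' @export
setMethod("coneVolume", "ConeModel",
  function(model) sum(model@segmentVolumesMm3))

#' Cross-sectional area profile of a cone model
#'
#' \eqn{\pi r(d)^2} with the radius linearly interpolated between knots,
#' sampled on a regular depth grid. This is the cutting-method counterpart
#' of [areaProfile()].
#'
#' @param model a [ConeModel-class].
#' @param depthStepMm sampling step in mm (default 1).
#' @return data.frame with columns `depth_mm` and `area_mm2`.
#' @export
setMethod("coneAreaProfile", "ConeModel",
  function(model, depthStepMm = 1) {
    k <- model@knots
    d <- seq(min(k$depth_mm), max(k$depth_mm), by = depthStepMm)
    r <- approx(k$depth_mm, k$radius_mm, xout = d)$y
    data.frame(depth_mm = d, area_mm2 = pi * r^2)
  })

#' Compare cutting-method and CT volumes
#'
#' Paired comparison of cavity volumes measured by the cutting method and
#' by CT on the same blocks: Pearson correlation, the relative differences
#' (cutting - CT) / CT, and a paired two-sided test (Wilcoxon signed-rank
#' by default, paired t as option) for a systematic offset.
#'
#' @param coneVolumes,ctVolumes paired numeric vectors of equal length
#'   (>= 3), same units.
#' @param test `"wilcoxon"` or `"t"`.
#' @return list with `pearson_r`, `mean_relative_diff`, `sd_relative_diff`,
#'   `p_value` and `n`.
#' @export
compareMethods <- function(coneVolumes, ctVolumes,
                           test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (length(coneVolumes) != length(ctVolumes))
    stop("paired lists must have equal length")
  if (length(coneVolumes) < 3L) stop("need at least 3 pairs")
  rel <- (coneVolumes - ctVolumes) / ctVolumes
  p <- if (identical(coneVolumes, ctVolumes)) 1 else if (test == "wilcoxon")
    suppressWarnings(wilcox.test(coneVolumes, ctVolumes,
                                 paired = TRUE)$p.value)
  else t.test(coneVolumes, ctVolumes, paired = TRUE)$p.value
  list(pearson_r = if (sd(coneVolumes) == 0 || sd(ctVolumes) == 0) NA_real_
         else cor(coneVolumes, ctVolumes),
       mean_relative_diff = mean(rel),
       sd_relative_diff = sd(rel),
       p_value = p, n = length(coneVolumes))
}

#' Sample cutting-method knots from a cavity profile
#'
#' Emulates the manual delineation of a cut-open block: the radius profile
#' is read off roughly every `spacingMm` of depth. Each recorded radius is
#' the local maximum of the profile within half a spacing of the click
#' (the delineator follows the visible cavity wall, which biases radii
#' upward), plus multiplicative measurement noise.
#'
#' @param profileFun function(depth) -> radius_mm.
#' @param lengthMm cavity length in mm.
#' @param spacingMm average distance between delineations (default 20 mm,
#'   i.e. one measurement per 2 cm).
#' @param noiseSd multiplicative noise standard deviation (default 0.03).
#' @param localMax take the local maximum around each click rather than the
#'   pointwise radius (default TRUE).
#' @return data.frame of knots suitable for [buildConeModel()].
#' @export
sampleCuttingKnots <- function(profileFun, lengthMm, spacingMm = 20,
                               noiseSd = 0.03, localMax = TRUE) {
  d <- seq(0, lengthMm, by = spacingMm)
  if (tail(d, 1) < lengthMm) d <- c(d, lengthMm)
  r <- vapply(d, function(di) {
    if (localMax) {
      w <- seq(max(0, di - spacingMm / 2), min(lengthMm, di + spacingMm / 2),
               length.out = 21)
      max(profileFun(w))
    } else profileFun(di)
  }, numeric(1))
  r <- r * exp(rnorm(length(r), 0, noiseSd))
  data.frame(depth_mm = d, radius_mm = pmax(r, 0))
}
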