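## Synthetic soap-block phantom generator.
##
## A phantom is a CT-like volume: a soap block (default +100 HU) surrounded
## by air (-1000 HU), containing an air-filled cavity modelled as a surface
## of revolution around a (possibly tilted) axis through the entry face,
## spherical metal fragments (default +3000 HU), optional streak artifacts
## near large fragments, and Gaussian acquisition noise. Every phantom
## carries analytic ground truth for recovery testing.

.cavityFamilies <- function() {
  c("tumbling_spindle", "early_opening", "tear_shaped", "cylinder",
    "ellipsoid")
}

## Family-specific parameter defaults. All lengths in mm. The shapes mirror
## the cavity phenomenology of the four bullet classes: a dimensionally
## stable bullet tumbles deep in the block (spindle bulge around 200 mm),
## a tip-activated bullet opens within the first quarter of the track, and
## deforming bullets produce a tear-shaped cavity.
.cavityParamDefaults <- function(family) {
  switch(family,
    cylinder = list(radius_mm = 10, length_mm = 100, tilt_deg = 0),
    ellipsoid = list(max_radius_mm = 25, length_mm = 200, tilt_deg = 0),
    tumbling_spindle = list(neck_radius_mm = 4, max_radius_mm = 30,
                            max_depth_mm = 200, length_mm = 300,
                            width_mm = 50, tilt_deg = 0),
    tear_shaped = list(neck_radius_mm = 4, max_radius_mm = 30,
                       max_depth_mm = 126, length_mm = 280, tilt_deg = 0),
    early_opening = list(neck_radius_mm = 4, max_radius_mm = 28,
                         length_mm = 260, tilt_deg = 0),
    stop(sprintf("unknown cavity family '%s'", family)))
}

#' Radius profile of a parametric cavity family
#'
#' Evaluates the cavity radius (mm) at one or more depths along the cavity
#' axis. All families are surfaces of revolution defined by a piecewise
#' smooth radius profile: `cylinder` is constant; `ellipsoid` is a prolate
#' spheroid; `tumbling_spindle` has a narrow entry channel and a Gaussian
#' bulge peaking at `max_depth_mm` (the tumbling depth); `tear_shaped`
#' rises smoothly to a maximum and tapers (a beta-shaped bulge peaking at
#' `max_depth_mm`); `early_opening` reaches near-maximal radius within the
#' first quarter of its length and then tapers.
#'
#' @param family cavity family name, see [phantomSpec()].
#' @param params named list of family parameters; missing entries fall back
#'   to family defaults.
#' @param depth numeric vector of depths (mm) along the axis, each within
#'   `[0, length_mm]`.
#' @return numeric vector of non-negative radii (mm).
#' @examples
#' cavityProfile("cylinder", list(radius_mm = 5, length_mm = 80), 40)
#' @export
cavityProfile <- function(family, params = list(), depth) {
  family <- match.arg(family, .cavityFamilies())
  p <- utils::modifyList(.cavityParamDefaults(family), params)
  L <- p$length_mm
  if (any(depth < -1e-9 | depth > L + 1e-9))
    stop("depth must lie within [0, length_mm]")
  depth <- pmin(pmax(depth, 0), L)
  r <- switch(family,
    cylinder = rep(p$radius_mm, length(depth)),
    ellipsoid = p$max_radius_mm * sqrt(pmax(0, 1 - (2 * depth / L - 1)^2)),
    tumbling_spindle = {
      bump <- exp(-((depth - p$max_depth_mm) / p$width_mm)^2)
      p$neck_radius_mm + (p$max_radius_mm - p$neck_radius_mm) * bump
    },
    tear_shaped = {
      u <- depth / L
      ustar <- p$max_depth_mm / L
      if (ustar <= 0 || ustar >= 1)
        stop("tear_shaped max_depth_mm must lie strictly inside (0, length)")
      a <- 2
      b <- a * (1 / ustar - 1)
      s <- (u^a * (1 - u)^b) / (ustar^a * (1 - ustar)^b)
      p$neck_radius_mm + (p$max_radius_mm - p$neck_radius_mm) * s
    },
    early_opening = {
      tau <- L / 16
      s <- (1 - exp(-depth / tau)) * (1 - (depth / L)^3)
      smax <- max((1 - exp(-seq(0, L, length.out = 512) / tau)) *
                    (1 - (seq(0, L, length.out = 512) / L)^3))
      p$neck_radius_mm + (p$max_radius_mm - p$neck_radius_mm) * s / smax
    })
  pmax(r, 0)
}

## Analytic cavity volume in mm^3: V = pi * integral of r(d)^2.
.cavityAnalyticVolumeMm3 <- function(family, params) {
  p <- utils::modifyList(.cavityParamDefaults(family), params)
  f <- function(d) pi * cavityProfile(family, p, d)^2
  stats::integrate(f, 0, p$length_mm, subdivisions = 2000L,
                   rel.tol = 1e-9)$value
}

## Maximal inscribed sphere of the parametric cavity (axis-symmetric search:
## the centre lies on the axis). The boundary consists of the lateral
## surface {(d, r(d))}, the entry plane at d = 0 and the end plane at d = L.
.trueMaxSphere <- function(family, params, step = 0.2) {
  p <- utils::modifyList(.cavityParamDefaults(family), params)
  L <- p$length_mm
  d <- seq(0, L, by = step)
  rd <- cavityProfile(family, p, d)
  best <- c(radius = -Inf, depth = NA_real_)
  for (d0 in d) {
    lateral <- min(sqrt((d - d0)^2 + rd^2))
    rad <- min(d0, L - d0, lateral)
    if (rad > best["radius"] + 1e-12) best <- c(radius = rad, depth = d0)
  }
  best
}

## Cavity must fit inside the block with a small clearance.
.checkCavityFits <- function(spec) {
  p <- utils::modifyList(.cavityParamDefaults(spec@cavityFamily),
                         spec@cavityParams)
  L <- p$length_mm
  tilt <- (p$tilt_deg %||% 0) * pi / 180
  d <- seq(0, L, length.out = 512)
  r <- cavityProfile(spec@cavityFamily, p, d)
  halfx <- spec@blockShapeMm[1] / 2
  halfy <- spec@blockShapeMm[2] / 2
  # lateral reach in x includes the tilt offset; y is unaffected by the tilt
  if (max(abs(d * sin(tilt)) + r) > halfx - 1 || max(r) > halfy - 1)
    return("cavity does not fit inside the block extents (x/y)")
  if (max(d * cos(tilt)) > spec@blockShapeMm[3] - 1)
    return("cavity longer than the block (z)")
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a synthetic soap-block phantom
#'
#' Builds a validated [PhantomSpec-class]. Defaults follow the rendering
#' conventions of clinical CT of glycerin soap: soap at +100 HU, air at
#' -1000 HU, metal fragments at +3000 HU (safely above the 2000 HU fragment
#' threshold), a 250 x 250 x 400 mm block at 1 mm isotropic voxels.
#'
#' @param blockShapeMm numeric(3), block extents in mm (z = shot axis).
#' @param voxelSpacingMm numeric(3) or scalar, voxel spacing in mm.
#' @param soapHu,airHu,fragmentHu rendering intensities (HU).
#' @param cavityFamily cavity shape family; see [cavityProfile()].
#' @param cavityParams named list of family parameters (radii, depths,
#'   `length_mm`, `tilt_deg`, ...); unspecified entries use family defaults.
#' @param nFragments number of spherical metal fragments.
#' @param fragmentRadiusRangeMm numeric(2), fragment radius range in mm.
#' @param streakArtifacts render streak spokes and high-intensity specks
#'   near fragments whose radius is above the median fragment radius.
#' @param noiseSdHu Gaussian noise standard deviation in HU.
#' @param marginMm air margin around the block in mm.
#' @param seed RNG seed; the rendered volume is bit-identical for a fixed
#'   seed.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(blockShapeMm = c(80, 80, 120), voxelSpacingMm = 2,
#'                     cavityFamily = "cylinder",
#'                     cavityParams = list(radius_mm = 8, length_mm = 90),
#'                     nFragments = 0L, noiseSdHu = 0)
#' spec
#' @export
phantomSpec <- function(blockShapeMm = c(250, 250, 400),
                        voxelSpacingMm = c(1, 1, 1),
                        soapHu = 100, airHu = -1000, fragmentHu = 3000,
                        cavityFamily = "tumbling_spindle",
                        cavityParams = list(),
                        nFragments = 0L,
                        fragmentRadiusRangeMm = c(1.5, 3.5),
                        streakArtifacts = FALSE,
                        noiseSdHu = 15, marginMm = 10, seed = 1L) {
  if (length(voxelSpacingMm) == 1L) voxelSpacingMm <- rep(voxelSpacingMm, 3)
  new("PhantomSpec",
      blockShapeMm = as.numeric(blockShapeMm),
      voxelSpacingMm = as.numeric(voxelSpacingMm),
      soapHu = as.numeric(soapHu), airHu = as.numeric(airHu),
      fragmentHu = as.numeric(fragmentHu),
      cavityFamily = cavityFamily, cavityParams = cavityParams,
      nFragments = as.integer(nFragments),
      fragmentRadiusRangeMm = as.numeric(fragmentRadiusRangeMm),
      streakArtifacts = isTRUE(streakArtifacts),
      noiseSdHu = as.numeric(noiseSdHu),
      marginMm = as.numeric(marginMm), seed = as.integer(seed))
}

#' Render a synthetic phantom with ground truth
#'
#' Voxelizes the parametric phantom described by a [PhantomSpec-class]:
#' block, cavity (a surface of revolution around the tilted axis through
#' the centre of the entry face), fragments placed in the soap just outside
#' the cavity wall, streak artifacts (thin radial spokes of alternating
#' +/-500 HU around large fragments, plus single-voxel high-intensity
#' specks within 5 mm that emulate streak debris), and Gaussian noise.
#' The run is deterministic for a fixed `seed` and leaves the caller's RNG
#' state untouched.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `volume` ([VoxelVolume-class]),
#'   `truth` ([PhantomTruth-class]), `blockMask` and `cavityMask`
#'   (noise-free rendered [BinaryMask-class] ground truth masks).
#' @examples
#' ph <- generatePhantom(phantomSpec(blockShapeMm = c(60, 60, 100),
#'   voxelSpacingMm = 2, cavityFamily = "cylinder",
#'   cavityParams = list(radius_mm = 8, length_mm = 80), noiseSdHu = 0))
#' ph$truth
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(spec@seed)

  sp <- spec@voxelSpacingMm
  m <- spec@marginMm
  B <- spec@blockShapeMm
  size <- B + 2 * m
  n <- pmax(2L, as.integer(ceiling(size / sp)))
  # voxel-centre coordinates; origin at half a voxel inside the physical box
  xc <- (seq_len(n[1]) - 0.5) * sp[1]
  yc <- (seq_len(n[2]) - 0.5) * sp[2]
  zc <- (seq_len(n[3]) - 0.5) * sp[3]
  origin <- sp / 2

  p <- utils::modifyList(.cavityParamDefaults(spec@cavityFamily),
                         spec@cavityParams)
  L <- p$length_mm
  tilt <- (p$tilt_deg %||% 0) * pi / 180
  u <- c(sin(tilt), 0, cos(tilt))
  p0 <- c(m + B[1] / 2, m + B[2] / 2, m) # centre of the entry face

  inx <- xc >= m & xc <= m + B[1]
  iny <- yc >= m & yc <= m + B[2]
  inz <- zc >= m & zc <= m + B[3]

  vol <- array(spec@airHu, dim = n)
  blockBox <- array(FALSE, dim = n)
  cavity <- array(FALSE, dim = n)

  dx <- xc - p0[1]
  dy2 <- (yc - p0[2])^2
  # dense profile lookup for fast vectorized evaluation per slice
  dprof <- seq(0, L, length.out = 4096L)
  rprof <- cavityProfile(spec@cavityFamily, p, dprof)
  rAt <- function(t) {
    r <- rep(0, length(t))
    ok <- t >= 0 & t <= L
    if (any(ok))
      r[ok] <- approx(dprof, rprof, xout = t[ok], rule = 2)$y
    r
  }

  for (k in seq_len(n[3])) {
    dz <- zc[k] - p0[3]
    if (inz[k]) blockBox[inx, iny, k] <- TRUE
    tax <- u[1] * dx + u[3] * dz
    ok <- tax >= 0 & tax <= L
    if (!any(ok)) next
    rt <- rAt(tax)
    # for each x: cavity iff dy^2 <= r(t)^2 - (dx^2 + dz^2 - t^2)
    rhs <- rt^2 - (dx^2 + dz^2 - tax^2)
    rhs[!ok] <- -Inf
    sl <- outer(rhs, dy2, `>=`)
    cavity[, , k] <- sl
  }
  cavity <- cavity & blockBox
  block <- blockBox & !cavity
  vol[block] <- spec@soapHu

  # ---- fragments: spheres in the soap just outside the cavity wall ----
  nf <- spec@nFragments
  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  if (nf > 0L) {
    rr <- spec@fragmentRadiusRangeMm
    e1 <- c(cos(tilt), 0, -sin(tilt)) # perpendicular basis of the axis
    e2 <- c(0, 1, 0)
    placed <- 0L
    tries <- 0L
    maxTries <- max(400L, 120L * nf)
    while (placed < nf && tries < maxTries) {
      tries <- tries + 1L
      frad <- runif(1, rr[1], rr[2])
      d0 <- runif(1, 0.25 * L, 0.95 * L)
      phi <- runif(1, 0, 2 * pi)
      gap <- runif(1, 2.5, 6)
      rho <- rAt(d0) + frad + gap
      ctr <- p0 + d0 * u + rho * (cos(phi) * e1 + sin(phi) * e2)
      lo <- c(m, m, m) + frad + 1
      hi <- c(m, m, m) + B - frad - 1
      if (any(ctr < lo) || any(ctr > hi)) next
      if (placed > 0L) { # keep fragments clearly separated
        dmin <- min(sqrt(rowSums(sweep(centers, 2, ctr)^2)))
        if (dmin < frad + max(radii) + 7) next
      }
      centers <- rbind(centers, ctr)
      radii <- c(radii, frad)
      placed <- placed + 1L
    }
    if (placed < nf)
      warning(sprintf("placed only %d of %d fragments", placed, nf))
    for (i in seq_len(placed)) {
      vol <- .paintSphere(vol, centers[i, ], radii[i], spec@fragmentHu,
                          xc, yc, zc)
    }
  }

  # ---- streak artifacts around fragments with radius above the median ----
  if (spec@streakArtifacts && length(radii) > 1L) {
    big <- which(radii > stats::median(radii))
    for (i in big) {
      angs <- runif(6, 0, 2 * pi)
      step <- mean(sp)
      for (a in angs) {
        dirv <- c(cos(a), sin(a), 0)
        dists <- seq(radii[i] + 1.8 * step, radii[i] + 5, by = step)
        sign <- 1
        for (dd in dists) {
          pt <- centers[i, ] + dd * dirv
          idx <- round((pt - origin) / sp) + 1
          if (any(idx < 1) || any(idx > n)) break
          if (!block[idx[1], idx[2], idx[3]]) break
          vol[idx[1], idx[2], idx[3]] <- spec@soapHu + sign * 500
          sign <- -sign
        }
      }
      # single-voxel high-intensity specks: streak debris near the fragment
      for (a in angs[1:2]) {
        dirv <- c(cos(a), sin(a), 0)
        dd <- radii[i] + runif(1, 2.2, 3.5)
        pt <- centers[i, ] + dd * dirv
        idx <- round((pt - origin) / sp) + 1
        if (all(idx >= 1) && all(idx <= n) &&
            block[idx[1], idx[2], idx[3]])
          vol[idx[1], idx[2], idx[3]] <- spec@fragmentHu
      }
    }
  }

  if (spec@noiseSdHu > 0)
    vol <- vol + array(rnorm(prod(n), 0, spec@noiseSdHu), dim = n)

  vv <- VoxelVolume(vol, spacing = sp, origin = origin)
  sph <- .trueMaxSphere(spec@cavityFamily, p)
  ctrMm <- p0 + sph[["depth"]] * u
  truth <- new("PhantomTruth",
    volumeMl = .cavityAnalyticVolumeMm3(spec@cavityFamily, p) / 1000,
    axis = u, tiltDeg = p$tilt_deg %||% 0,
    fragmentCentersMm = centers, fragmentRadiiMm = radii,
    sphereRadiusMm = sph[["radius"]],
    sphereDepthMm = sph[["depth"]] * cos(tilt),
    sphereCenterMm = ctrMm, entryZMm = m)
  list(volume = vv, truth = truth,
       blockMask = BinaryMask(block, template = vv),
       cavityMask = BinaryMask(cavity, template = vv))
}

## paint a sphere of constant intensity into vol (voxel-centre inclusion)
.paintSphere <- function(vol, center, radius, value, xc, yc, zc) {
  ix <- which(abs(xc - center[1]) <= radius)
  iy <- which(abs(yc - center[2]) <= radius)
  iz <- which(abs(zc - center[3]) <= radius)
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  sub <- expand.grid(x = ix, y = iy, z = iz)
  d2 <- (xc[sub$x] - center[1])^2 + (yc[sub$y] - center[2])^2 +
    (zc[sub$z] - center[3])^2
  keep <- d2 <= radius^2
  vol[cbind(sub$x[keep], sub$y[keep], sub$z[keep])] <- value
  vol
}

#' Enumerate a shot design
#'
#' Expands a factorial design of bullet types, per-bullet impact speeds and
#' repetitions into one shot stub per (bullet, speed, repetition), in
#' deterministic order: bullets in input order, speeds ascending,
#' repetition index last.
#'
#' @param bullets character vector of bullet identifiers.
#' @param speeds numeric vector of impact speeds (m/s) applied to every
#'   bullet, or a named list with one speed vector per bullet.
#' @param repetitions number of shots per (bullet, speed) configuration.
#' @return data.frame with columns `bullet`, `speed_mps`, `repetition`.
#' @examples
#' d <- enumerateDesign(c("ILS", "TAG"), list(ILS = c(600, 700),
#'                                            TAG = c(550, 650)), 2)
#' nrow(d) # 8
#' @export
enumerateDesign <- function(bullets, speeds, repetitions = 1L) {
  if (length(bullets) == 0L) stop("bullet list must not be empty")
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop("repetitions must be >= 1")
  if (!is.list(speeds)) speeds <- setNames(rep(list(speeds), length(bullets)),
                                           bullets)
  rows <- lapply(bullets, function(b) {
    sp <- sort(as.numeric(speeds[[b]]))
    if (length(sp) == 0L) stop(sprintf("bullet '%s' has no speeds", b))
    expand.grid(repetition = seq_len(repetitions), speed_mps = sp,
                bullet = b, stringsAsFactors = FALSE)[, 3:1]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
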