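## Threshold-based region-growing segmentation of block, cavity and
## fragments, plus the streak-artifact exclusion rule.
##
## Thresholds follow the CT workflow for soap blocks: the block is all
## connected tissue-simulant above 50% of the (estimated) soap intensity;
## the cavity is connected sub-threshold air enclosed by the block within a
## user-chosen slice range; metal fragments are connected components above
## a fixed 2000 HU threshold. Connectivity: 6 for block/cavity region
## growing, 26 for fragments (small, possibly diagonal specks).

#' Estimate the soap intensity of a scan
#'
#' Robust central estimate used by the relative 50% segmentation threshold:
#' a two-class Otsu split of the intensity histogram separates air from
#' denser material, and the median of the upper class (soap plus a handful
#' of metal voxels, which do not move the median) is returned.
#'
#' @param volume a [VoxelVolume-class].
#' @return Estimated soap intensity in HU.
#' @examples
#' ph <- generatePhantom(phantomSpec(blockShapeMm = c(60, 60, 80),
#'   voxelSpacingMm = 2, cavityFamily = "cylinder",
#'   cavityParams = list(radius_mm = 6, length_mm = 60), noiseSdHu = 0))
#' estimateSoapIntensity(ph$volume) # 100
#' @export
estimateSoapIntensity <- function(volume) {
  stopifnot(is(volume, "VoxelVolume"))
  v <- voxelData(volume)
  rng <- range(v)
  if (diff(rng) < 1e-9)
    stop("degenerate volume: constant intensity, cannot estimate soap")
  thr <- .otsuThreshold(v)
  upper <- v[v > thr]
  if (!length(upper)) stop("no voxels above the air/soap split")
  median(upper)
}

## Otsu's two-class threshold on a 512-bin histogram.
.otsuThreshold <- function(v) {
  nb <- 512L
  rng <- range(v)
  h <- tabulate(pmin(nb, 1L + as.integer((v - rng[1]) / diff(rng) * nb)), nb)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nb) - 0.5) * diff(rng) / nb
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nb]
  sigma2 <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sigma2[!is.finite(sigma2)] <- -Inf
  mids[which.max(sigma2)]
}

#' Segment the soap block
#'
#' Fixed relative threshold: voxels at or above 50% of the soap intensity,
#' reduced to the largest 6-connected component. Metal fragments embedded
#' in the soap are part of the block; cavity air is below threshold and
#' excluded.
#'
#' @param volume a [VoxelVolume-class].
#' @param soapHu soap intensity; estimated with [estimateSoapIntensity()]
#'   when `NULL`.
#' @param thresholdFraction fraction of the soap intensity used as the
#'   lower bound (default 0.5).
#' @return A [BinaryMask-class] of the block.
#' @export
setMethod("segmentBlock", "VoxelVolume",
  function(volume, soapHu = NULL, thresholdFraction = 0.5) {
    if (is.null(soapHu)) soapHu <- estimateSoapIntensity(volume)
    thr <- thresholdFraction * soapHu
    v <- voxelData(volume)
    fg <- v >= thr
    if (!any(fg)) stop("no block found: no voxel above threshold")
    lab <- cpp_label_components(as.logical(fg), dim(v), 6L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)
    BinaryMask(array(lab == keep, dim = dim(v)), template = volume)
  })

## seeds for cavity growing: interior air of one slice = air components
## (4-connected, in-plane) that do not touch the slice border. Returns
## linear indices into the full 3D array, or integer(0).
.interiorAirSeeds <- function(air3d, k) {
  d <- dim(air3d)
  sl <- air3d[, , k, drop = FALSE]
  lab <- cpp_label_components(as.logical(sl), c(d[1], d[2], 1L), 6L)
  if (max(lab) == 0L) return(integer(0))
  border <- unique(c(lab[1, , 1], lab[d[1], , 1], lab[, 1, 1], lab[, d[2], 1]))
  interior <- setdiff(seq_len(max(lab)), border)
  if (!length(interior)) return(integer(0))
  idx2d <- which(array(lab, dim = c(d[1], d[2])) %in% interior)
  idx2d + (k - 1L) * d[1] * d[2]
}

#' Segment the wound cavity
#'
#' Region growing of sub-threshold (air) voxels enclosed by the block,
#' restricted to an axial slice range. Seeds are found automatically in the
#' first slice: air regions enclosed by the block cross-section (air not
#' reachable from the slice border). With `firstSlice = NULL` the fully
#' automatic mode is used instead: the largest interior air component
#' within the block's axial extent.
#'
#' @param volume a [VoxelVolume-class].
#' @param blockMask the block segmentation from [segmentBlock()].
#' @param firstSlice,lastSlice 1-based indices of the first and last axial
#'   (z) slices of the cavity; both `NULL` for the automatic mode.
#' @param soapHu soap intensity; estimated when `NULL`.
#' @param thresholdFraction fraction of the soap intensity below which a
#'   voxel counts as air (default 0.5).
#' @return A [BinaryMask-class] of the cavity (largest connected
#'   component).
#' @export
setMethod("segmentCavity", c("VoxelVolume", "BinaryMask"),
  function(volume, blockMask, firstSlice = NULL, lastSlice = NULL,
           soapHu = NULL, thresholdFraction = 0.5) {
    if (!identical(gridDim(volume), gridDim(blockMask)))
      stop("block mask is not on the volume's grid")
    if (is.null(soapHu)) soapHu <- estimateSoapIntensity(volume)
    thr <- thresholdFraction * soapHu
    v <- voxelData(volume)
    d <- dim(v)
    block <- .maskBits(blockMask)

    auto <- is.null(firstSlice) && is.null(lastSlice)
    if (auto) {
      zAny <- which(colSums(matrix(block, ncol = d[3])) > 0)
      firstSlice <- min(zAny)
      lastSlice <- max(zAny)
    }
    firstSlice <- as.integer(firstSlice)
    lastSlice <- as.integer(lastSlice)
    if (firstSlice > lastSlice) stop("firstSlice must be <= lastSlice")
    if (firstSlice < 1L || lastSlice > d[3]) stop("slice range out of bounds")

    air <- v < thr
    if (!any(air[, , firstSlice:lastSlice]))
      stop("no cavity found: no sub-threshold voxels in the slice range")

    # confine growth to the slice range by masking the rest as non-air
    vwork <- v
    if (firstSlice > 1L) vwork[, , seq_len(firstSlice - 1L)] <- Inf
    if (lastSlice < d[3]) vwork[, , seq(lastSlice + 1L, d[3])] <- Inf

    if (auto) {
      # all interior air components in the block's axial extent; pick largest
      lab <- cpp_label_components(
        as.logical(array(vwork < thr, dim = d)), d, 6L)
      if (max(lab) > 0L) {
        borderLabs <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ],
                               lab[, d[2], ]))
        interior <- setdiff(seq_len(max(lab)), borderLabs)
        if (!length(interior)) stop("no cavity found: only exterior air")
        sizes <- tabulate(lab[lab > 0L], max(lab))
        keep <- interior[which.max(sizes[interior])]
        return(BinaryMask(array(lab == keep, dim = d), template = volume))
      }
      stop("no cavity found")
    }

    # bounding-box sanity for the seeded mode
    bb <- which(block[, , firstSlice], arr.ind = TRUE)
    if (!nrow(bb))
      stop("firstSlice does not intersect the block; seeds would fall ",
           "outside the block bounding box")
    seeds <- .interiorAirSeeds(array(vwork < thr, dim = d), firstSlice)
    if (!length(seeds))
      stop("no cavity found: no enclosed air in the first slice")
    grown <- cpp_region_grow(as.numeric(vwork), d, as.numeric(seeds),
                             -Inf, thr, 6L)
    lab <- cpp_label_components(grown, d, 6L)
    if (max(lab) == 0L) stop("no cavity found")
    sizes <- tabulate(lab[lab > 0L])
    BinaryMask(array(lab == which.max(sizes), dim = d), template = volume)
  })

#' Segment metal fragments
#'
#' Connected components (26-connectivity) of voxels above the fixed
#' fragment threshold of 2000 HU, labelled deterministically by centroid
#' (z, then y, then x) with per-fragment statistics. An empty fragment set
#' is allowed.
#'
#' @param volume a [VoxelVolume-class].
#' @param thresholdHu fragment threshold (default 2000 HU).
#' @return A [FragmentSet-class]; all fragments start with
#'   `counted = TRUE`.
#' @seealso [applyStreakExclusion()]
#' @export
setMethod("segmentFragments", "VoxelVolume",
  function(volume, thresholdHu = 2000) {
    v <- voxelData(volume)
    d <- dim(v)
    sp <- voxelSpacing(volume)
    fg <- v > thresholdHu
    lab <- cpp_label_components(as.logical(fg), d, 26L)
    nlab <- max(lab)
    if (nlab == 0L) {
      tab <- data.frame(label = integer(0), n_voxels = integer(0),
                        volume_mm3 = numeric(0), centroid_x_mm = numeric(0),
                        centroid_y_mm = numeric(0), centroid_z_mm = numeric(0),
                        max_hu = numeric(0), counted = logical(0))
      return(new("FragmentSet", table = tab, labels = lab,
                 spacing = sp, origin = voxelOrigin(volume)))
    }
    st <- cpp_component_stats(lab, d, as.numeric(v), nlab)
    org <- voxelOrigin(volume)
    cen <- cbind(org[1] + st$cx * sp[1], org[2] + st$cy * sp[2],
                 org[3] + st$cz * sp[3])
    ord <- order(cen[, 3], cen[, 2], cen[, 1])
    # relabel 1..n in (z, y, x) centroid order
    relab <- integer(nlab)
    relab[ord] <- seq_len(nlab)
    lut <- c(0L, relab) # maps stored label value (0..nlab) to new label
    lab2 <- array(lut[lab + 1L], dim = d)
    storage.mode(lab2) <- "integer"
    tab <- data.frame(
      label = seq_len(nlab),
      n_voxels = as.integer(st$count[ord]),
      volume_mm3 = st$count[ord] * prod(sp),
      centroid_x_mm = cen[ord, 1], centroid_y_mm = cen[ord, 2],
      centroid_z_mm = cen[ord, 3],
      max_hu = st$max[ord], counted = TRUE)
    new("FragmentSet", table = tab, labels = lab2, spacing = sp,
        origin = voxelOrigin(volume))
  })

#' Exclude streak-artifact specks from the fragment count
#'
#' Small fragments close to larger fragments are likely streak artifacts of
#' the CT reconstruction rather than real metal, and are flagged as not
#' counted (they remain in the table). A fragment is "small" when its
#' volume is at most `smallMaxMm3`; it is excluded when its distance to the
#' nearest larger-than-small fragment is at most `proximityMm`.
#'
#' @param fragments a [FragmentSet-class] from [segmentFragments()].
#' @param smallMaxMm3 largest volume (mm^3) still considered a speck
#'   (default 8).
#' @param proximityMm exclusion distance in mm (default 5).
#' @return The [FragmentSet-class] with updated `counted` flags.
#' @export
applyStreakExclusion <- function(fragments, smallMaxMm3 = 8,
                                 proximityMm = 5) {
  stopifnot(is(fragments, "FragmentSet"))
  if (smallMaxMm3 < 0 || proximityMm < 0)
    stop("smallMaxMm3 and proximityMm must be non-negative")
  tab <- fragments@table
  tab$counted <- rep(TRUE, nrow(tab))
  if (nrow(tab) < 2L) {
    fragments@table <- tab
    return(fragments)
  }
  small <- tab$label[tab$volume_mm3 <= smallMaxMm3]
  large <- tab$label[tab$volume_mm3 > smallMaxMm3]
  if (!length(small) || !length(large)) {
    fragments@table <- tab
    return(fragments)
  }
  lab <- fragments@labels
  sp <- voxelSpacing(fragments)
  # all fragments live in a small part of the grid: crop to their bounding
  # box padded by the proximity radius before transforming
  pad <- as.integer(ceiling(proximityMm / min(sp))) + 1L
  bb <- .maskBBox(lab > 0L, pad = pad)
  sub <- lab[bb$x[1]:bb$x[2], bb$y[1]:bb$y[2], bb$z[1]:bb$z[2],
             drop = FALSE]
  notLarge <- array(!(sub %in% large), dim = dim(sub))
  # distance of every voxel to the nearest large-fragment voxel; the grid
  # border is NOT background here (distances must come from fragments only)
  dist <- cpp_edt(as.logical(notLarge), dim(sub), sp, FALSE)
  for (l in small) {
    md <- min(dist[sub == l])
    if (is.finite(md) && md <= proximityMm)
      tab$counted[tab$label == l] <- FALSE
  }
  fragments@table <- tab
  fragments
}

#' @describeIn FragmentSet-class per-fragment statistics table.
#' @export
setMethod("fragmentTable", "FragmentSet", function(x) x@table)

#' @describeIn FragmentSet-class number of fragments with `counted = TRUE`.
#' @export
setMethod("countedFragments", "FragmentSet",
  function(x) sum(x@table$counted))
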