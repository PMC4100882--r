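## End-to-end orchestration: a synthetic study mirroring the experimental
## design (4 bullet types x 4 impact speeds x repetitions), from phantom
## generation through segmentation, morphometry and the statistical
## comparisons, into one deterministic study report.

#' Default bullet catalogue for synthetic studies
#'
#' The four 7.62 mm bullet types of the experimental design with their
#' masses, per-type impact speeds, cavity family, exit-mass model and the
#' volume-energy law used to generate phantom cavities: the dimensionally
#' stable (ILS, brass, tumbling) and fragmenting (TAG, copper, tip-opened)
#' types follow a linear law, the deforming types (TSX copper, NVU
#' lead-core) a convex quadratic law. Fragment counts grow with deposited
#' energy; the lead-core bullet sheds by far the most.
#'
#' @return data.frame with one row per bullet type.
#' @export
defaultBulletCatalogue <- function() {
  data.frame(
    bullet = c("ILS", "TAG", "TSX", "NVU"),
    material = c("Brass", "Copper", "Copper", "Lead/Copper"),
    type = c("Dimensionally stable", "Fragmenting", "Deforming",
             "Deforming"),
    caliber_mm = 7.62,
    mass_g = c(8.45, 10.07, 10.71, 11.68),
    family = c("tumbling_spindle", "early_opening", "tear_shaped",
               "tear_shaped"),
    exit_fraction_max = c(0.994, 0.649, 0.736, 0.547),
    tilt_mean_deg = c(6, 1.5, 1.5, 1.5),
    tilt_sd_deg = c(0.5, 0.4, 0.4, 0.4),
    law = c("linear", "linear", "quadratic", "quadratic"),
    law_a = c(0.10, 0.10, 0.04, 0.04),
    law_b = c(0, 0, 2.5e-5, 2.5e-5),
    frag_base = c(0, 2, 4, 12),
    frag_per_kj = c(0, 1.7, 2.5, 6.7),
    streaks = c(FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

.defaultSpeeds <- function() {
  list(ILS = c(600, 700, 800, 900), TAG = c(550, 650, 750, 850),
       TSX = c(550, 650, 750, 850), NVU = c(500, 600, 700, 800))
}

#' Configuration of a synthetic study
#'
#' Collects everything that determines a study run: the bullet catalogue
#' (each bullet maps to exactly one cavity family), per-bullet speed lists,
#' repetitions, phantom geometry and noise, segmentation parameters,
#' statistics options and the master seed. A fixed seed fully determines
#' the run.
#'
#' @param catalogue bullet catalogue; see [defaultBulletCatalogue()].
#' @param speeds named list of impact speeds (m/s) per bullet.
#' @param repetitions shots per (bullet, speed) configuration (default 2).
#' @param blockShapeMm,voxelSpacingMm phantom block geometry (mm); the
#'   defaults (150 x 150 x 300 mm at 2 mm voxels) keep a full study fast
#'   while leaving segmentation non-trivial.
#' @param noiseSdHu CT noise (HU).
#' @param repNoiseSd multiplicative shot-to-shot variability of the cavity
#'   volume (lognormal sd, default 0.05).
#' @param exitSpeedFraction exit speed as a fraction of impact speed.
#' @param smallFragmentMm3,proximityMm streak-exclusion parameters.
#' @param alpha significance level.
#' @param seed master RNG seed.
#' @param outDir output directory for CSV/JSON artifacts, or `NULL`.
#' @return A list of class `StudyConfig`.
#' @export
studyConfig <- function(catalogue = defaultBulletCatalogue(),
                        speeds = .defaultSpeeds(),
                        repetitions = 2L,
                        blockShapeMm = c(150, 150, 300),
                        voxelSpacingMm = 2,
                        noiseSdHu = 10,
                        repNoiseSd = 0.05,
                        exitSpeedFraction = 0.15,
                        smallFragmentMm3 = 8,
                        proximityMm = 5,
                        alpha = 0.05,
                        seed = 1L,
                        outDir = NULL) {
  if (anyDuplicated(catalogue$bullet))
    stop("each bullet must map to exactly one cavity family")
  if (!all(catalogue$bullet %in% names(speeds)))
    stop("every bullet needs a speed list")
  if (!all(catalogue$family %in% .cavityFamilies()))
    stop("unknown cavity family in catalogue")
  structure(list(
    catalogue = catalogue, speeds = speeds,
    repetitions = as.integer(repetitions),
    blockShapeMm = blockShapeMm,
    voxelSpacingMm = voxelSpacingMm,
    noiseSdHu = noiseSdHu, repNoiseSd = repNoiseSd,
    exitSpeedFraction = exitSpeedFraction,
    smallFragmentMm3 = smallFragmentMm3, proximityMm = proximityMm,
    alpha = alpha, seed = as.integer(seed), outDir = outDir),
    class = "StudyConfig")
}

## family parameters for a study phantom, scaled so the analytic cavity
## volume matches the target (solve for the maximal radius)
.familyParamsForVolume <- function(family, targetMl, blockShapeMm,
                                   tiltDeg) {
  L <- 0.85 * blockShapeMm[3]
  base <- switch(family,
    tumbling_spindle = list(neck_radius_mm = 4, max_depth_mm = min(200, 0.78 * L),
                            length_mm = L, width_mm = L / 6,
                            tilt_deg = tiltDeg),
    early_opening = list(neck_radius_mm = 4, length_mm = L,
                         tilt_deg = tiltDeg),
    tear_shaped = list(neck_radius_mm = 4, max_depth_mm = 0.45 * L,
                       length_mm = L, tilt_deg = tiltDeg),
    ellipsoid = list(length_mm = L, tilt_deg = tiltDeg),
    stop(sprintf("family '%s' not supported in studies", family)))
  rmaxFeasible <- min(blockShapeMm[1:2]) / 2 - 2 -
    L * sin(tiltDeg * pi / 180)
  volAt <- function(rmax) {
    .cavityAnalyticVolumeMm3(family,
      utils::modifyList(base, list(max_radius_mm = rmax))) / 1000
  }
  if (volAt(rmaxFeasible) < targetMl) {
    warning(sprintf("target volume %.0f mL capped at feasible %.0f mL",
                    targetMl, volAt(rmaxFeasible)))
    rmax <- rmaxFeasible
  } else {
    rmax <- uniroot(function(r) volAt(r) - targetMl,
                    c(4.5, rmaxFeasible), tol = 1e-4)$root
  }
  utils::modifyList(base, list(max_radius_mm = rmax))
}

#' Analyze one soap-block scan
#'
#' Runs the full single-block pipeline: soap-intensity estimation, block
#' segmentation, cavity segmentation (automatic mode unless slice indices
#' are given), fragment segmentation with streak exclusion, and cavity
#' morphometry. When shot metadata is supplied, deposited energy is
#' attached to the returned record.
#'
#' @param volume a [VoxelVolume-class], or a path readable by
#'   [readVolume()].
#' @param shotMetadata optional one-row data.frame (or list) with
#'   `mass_initial_g`, `speed_in_mps`, `mass_exit_g`, `speed_out_mps` and
#'   any identifying columns.
#' @param firstSlice,lastSlice manual cavity slice range; `NULL` for
#'   automatic cavity detection.
#' @param smallFragmentMm3,proximityMm streak-exclusion parameters.
#' @return list with `metrics` ([CavityMetrics-class]), `fragments`
#'   ([FragmentSet-class]), `blockMask`, `cavityMask` and `record` (one-row
#'   data.frame of scalar results).
#' @export
analyzeShot <- function(volume, shotMetadata = NULL, firstSlice = NULL,
                        lastSlice = NULL, smallFragmentMm3 = 8,
                        proximityMm = 5) {
  if (is.character(volume)) volume <- readVolume(volume)
  stopifnot(is(volume, "VoxelVolume"))
  soap <- estimateSoapIntensity(volume)
  block <- segmentBlock(volume, soapHu = soap)
  cavity <- segmentCavity(volume, block, firstSlice = firstSlice,
                          lastSlice = lastSlice, soapHu = soap)
  frags <- segmentFragments(volume)
  frags <- applyStreakExclusion(frags, smallMaxMm3 = smallFragmentMm3,
                                proximityMm = proximityMm)
  metrics <- cavityMetrics(cavity, block)
  record <- data.frame(
    soap_hu = soap,
    cavity_volume_ml = metrics@volumeMl,
    deflection_deg = metrics@deflectionDeg,
    max_sphere_radius_mm = metrics@sphereRadiusMm,
    max_damage_depth_mm = metrics@maxDamageDepthMm,
    fragments_raw = nrow(fragmentTable(frags)),
    fragments_counted = countedFragments(frags))
  if (!is.null(shotMetadata)) {
    md <- as.data.frame(shotMetadata)
    if (all(c("mass_initial_g", "speed_in_mps") %in% names(md))) {
      md$deposited_energy_j <- depositedEnergy(
        md$mass_initial_g, md$speed_in_mps,
        md$mass_exit_g %||% 0, md$speed_out_mps %||% 0)
    }
    record <- cbind(md, record)
  }
  list(metrics = metrics, fragments = frags, blockMask = block,
       cavityMask = cavity, record = record)
}

#' Run a full synthetic study
#'
#' Expands the design into shots, generates one phantom per shot (cavity
#' volume drawn from the bullet's volume-energy law with shot-to-shot
#' noise), analyzes every block with [analyzeShot()], samples
#' cutting-method delineations from each true cavity profile, and computes
#' the study-level statistics: per-bullet through-origin fits with AIC
#' selection, ANCOVA on volume-to-energy ratios, one-way ANOVA with Tukey
#' HSD on deflection angle and depth of maximal damage, reproducibility
#' correlations between first and second shots, and the cutting-vs-CT
#' comparison. The run is fully determined by `config$seed`; with
#' `outDir` set, per-shot and fragment tables (CSV) and the report (JSON)
#' are written.
#'
#' @param config a [studyConfig()].
#' @return The study report (list), invisibly also written to
#'   `config$outDir` when set.
#' @export
runStudy <- function(config = studyConfig()) {
  stopifnot(inherits(config, "StudyConfig"))
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(config$seed)

  catl <- config$catalogue
  design <- enumerateDesign(catl$bullet, config$speeds, config$repetitions)
  n <- nrow(design)
  shotSeeds <- sample.int(2147483646L, n)
  repNoise <- exp(rnorm(n, 0, config$repNoiseSd))
  tiltDraw <- rnorm(n)
  knotNoiseSeeds <- sample.int(2147483646L, n)

  shots <- vector("list", n)
  fragTables <- vector("list", n)
  for (i in seq_len(n)) {
    b <- catl[catl$bullet == design$bullet[i], ]
    v <- design$speed_mps[i]
    vmax <- max(config$speeds[[b$bullet]])
    mExit <- b$exit_fraction_max * b$mass_g * (v / vmax)^2
    vOut <- config$exitSpeedFraction * v
    energy <- depositedEnergy(b$mass_g, v, mExit, vOut)
    targetMl <- (b$law_a * energy + b$law_b * energy^2) * repNoise[i]
    tilt <- max(0.2, b$tilt_mean_deg + b$tilt_sd_deg * tiltDraw[i])
    nFrag <- as.integer(round(b$frag_base + b$frag_per_kj * energy / 1000))

    res <- tryCatch({
      params <- .familyParamsForVolume(b$family, targetMl,
                                       config$blockShapeMm, tilt)
      spec <- phantomSpec(
        blockShapeMm = config$blockShapeMm,
        voxelSpacingMm = config$voxelSpacingMm,
        cavityFamily = b$family, cavityParams = params,
        nFragments = nFrag,
        fragmentRadiusRangeMm = c(2.2, 3.6),
        streakArtifacts = b$streaks,
        noiseSdHu = config$noiseSdHu,
        seed = shotSeeds[i])
      ph <- generatePhantom(spec)
      an <- analyzeShot(ph$volume,
                        smallFragmentMm3 = config$smallFragmentMm3,
                        proximityMm = config$proximityMm)
      # cutting method: sparse delineation of the true cavity silhouette
      set.seed(knotNoiseSeeds[i])
      knots <- sampleCuttingKnots(
        function(d) cavityProfile(b$family, params, d),
        lengthMm = params$length_mm)
      cut <- buildConeModel(knots)
      list(an = an, truth = ph$truth, cuttingMl = coneVolume(cut) / 1000)
    }, error = function(e) {
      stop(sprintf("shot %d (%s %d m/s rep %d) failed: %s", i,
                   design$bullet[i], design$speed_mps[i],
                   design$repetition[i], conditionMessage(e)), call. = FALSE)
    })

    rec <- data.frame(
      shot = i, bullet = b$bullet, speed_mps = v,
      repetition = design$repetition[i],
      mass_initial_g = b$mass_g, mass_exit_g = mExit,
      speed_out_mps = vOut, deposited_energy_j = energy,
      true_volume_ml = res$truth@volumeMl,
      true_tilt_deg = res$truth@tiltDeg,
      cutting_volume_ml = res$cuttingMl)
    shots[[i]] <- cbind(rec, res$an$record)
    ft <- fragmentTable(res$an$fragments)
    if (nrow(ft)) ft <- cbind(shot = i, ft)
    fragTables[[i]] <- ft
  }
  shots <- do.call(rbind, shots)
  shots$volume_energy_ratio_ml_per_j <-
    energyVolumeRatio(shots$cavity_volume_ml, shots$deposited_energy_j)

  # ---- study-level statistics ----
  fits <- lapply(catl$bullet, function(bn) {
    s <- shots[shots$bullet == bn, ]
    fl <- fitThroughOrigin(s$deposited_energy_j, s$cavity_volume_ml, 1)
    fq <- fitThroughOrigin(s$deposited_energy_j, s$cavity_volume_ml, 2)
    sel <- aicSelect(fl, fq)
    list(bullet = bn,
         linear = list(coef = as.list(fl@coefficients),
                       r_squared = fl@rSquared, aic = fl@aic),
         quadratic = list(coef = as.list(fq@coefficients),
                          r_squared = fq@rSquared, aic = fq@aic),
         preferred = sel$preferred, delta_aic = sel$delta_aic)
  })
  names(fits) <- catl$bullet

  ratioGroups <- lapply(split(shots, shots$bullet), function(s)
    list(x = s$deposited_energy_j, y = s$volume_energy_ratio_ml_per_j))
  ancova <- ancovaSlopes(ratioGroups)

  angleGroups <- split(shots$deflection_deg, shots$bullet)
  depthGroups <- split(shots$max_damage_depth_mm, shots$bullet)
  anovaAngle <- anovaTukey(angleGroups)
  anovaDepth <- anovaTukey(depthGroups)

  repro <- NULL
  if (config$repetitions >= 2L) {
    s1 <- shots[shots$repetition == 1L, ]
    s2 <- shots[shots$repetition == 2L, ]
    key <- paste(s1$bullet, s1$speed_mps)
    key2 <- paste(s2$bullet, s2$speed_mps)
    s2 <- s2[match(key, key2), ]
    repro <- reproducibilityCorrelation(
      s1$cavity_volume_ml, s2$cavity_volume_ml, group = s1$bullet)
    reproCut <- reproducibilityCorrelation(
      s1$cutting_volume_ml, s2$cutting_volume_ml)
    repro$r_cutting <- reproCut$r
  } else {
    warning("repetitions = 1: reproducibility section omitted")
  }

  cutCmp <- compareMethods(shots$cutting_volume_ml, shots$cavity_volume_ml)

  allFrags <- do.call(rbind, fragTables[vapply(fragTables, nrow, 1L) > 0])
  report <- list(
    study = list(seed = config$seed, n_shots = n,
                 n_configurations = nrow(unique(design[, 1:2])),
                 repetitions = config$repetitions,
                 voxel_spacing_mm = config$voxelSpacingMm,
                 block_shape_mm = config$blockShapeMm,
                 alpha = config$alpha),
    shots = shots,
    fits = fits,
    ancova_ratio_slopes = ancova,
    anova_deflection = anovaAngle,
    anova_depth = anovaDepth,
    reproducibility = repro,
    cutting_vs_ct = cutCmp,
    totals = list(shots = nrow(shots),
                  fragments_counted = sum(shots$fragments_counted),
                  fragments_raw = sum(shots$fragments_raw)))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(shots, file.path(config$outDir, "shots.csv"),
              row.names = FALSE)
    if (!is.null(allFrags))
      write.csv(allFrags, file.path(config$outDir, "fragments.csv"),
                row.names = FALSE)
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  report
}
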