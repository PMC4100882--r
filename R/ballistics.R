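## Shot-level bookkeeping: deposited energy, unit conversions, ratios.

# exact avoirdupois definition
.GRAMS_PER_GRAIN <- 0.06479891

#' Deposited energy of a shot
#'
#' Kinetic energy released inside the block: entry kinetic energy minus the
#' kinetic energy of the exiting fragments,
#' \eqn{E = m_{in} v_{in}^2 / 2 - m_{exit} v_{exit}^2 / 2}
#' with masses in grams (converted to kg) and speeds in m/s. When nothing
#' exits, pass zero exit mass and speed.
#'
#' @param massInitialG initial bullet mass in g.
#' @param speedInMps impact speed in m/s.
#' @param massExitG exiting fragment mass in g (0 if no exit).
#' @param speedOutMps exit speed in m/s (0 if no exit).
#' @return Deposited energy in joules. Vectorized.
#' @examples
#' depositedEnergy(10, 800, 0, 0)    # 3200 J, full deposition
#' depositedEnergy(10, 800, 6, 100)  # 3170 J
#' @export
depositedEnergy <- function(massInitialG, speedInMps, massExitG = 0,
                            speedOutMps = 0) {
  if (any(speedInMps < 0) || any(speedOutMps < 0))
    stop("speeds must be non-negative")
  if (any(massExitG < 0) || any(massExitG > massInitialG))
    stop("exit mass must lie in [0, initial mass]")
  0.5 * massInitialG / 1000 * speedInMps^2 -
    0.5 * massExitG / 1000 * speedOutMps^2
}

#' Convert grams to grains
#'
#' Bullet weights are conventionally quoted in grains
#' (1 gr = 0.06479891 g exactly). Rounded to 2 decimals for display, as in
#' ammunition catalogues.
#'
#' @param massG mass in grams (vectorized, non-negative).
#' @param digits decimals for rounding (default 2; `NA` for no rounding).
#' @return Mass in grains.
#' @examples
#' gramsToGrains(8.45) # 130.40
#' @export
gramsToGrains <- function(massG, digits = 2) {
  if (any(massG < 0)) stop("mass must be non-negative")
  gr <- massG / .GRAMS_PER_GRAIN
  if (is.na(digits)) gr else round(gr, digits)
}

#' Relative weight of the exiting fragments
#'
#' Exiting mass as a percentage of the initial bullet mass; high values
#' mean the bullet stayed intact (dimensionally stable), low values mean
#' strong fragmentation or mass retention in the block.
#'
#' @param massInitialG initial mass in g (> 0).
#' @param massExitG exiting mass in g, within [0, massInitialG].
#' @return Percentage in [0, 100]. Vectorized.
#' @export
retainedMassFraction <- function(massInitialG, massExitG) {
  if (any(massInitialG <= 0)) stop("initial mass must be positive")
  if (any(massExitG < 0) || any(massExitG > massInitialG))
    stop("exit mass must lie in [0, initial mass]")
  100 * massExitG / massInitialG
}

#' Volume-to-energy conversion ratio
#'
#' Cavity volume per deposited joule (mL/J). A constant ratio over energy
#' indicates a linear volume-energy law; a ratio increasing with energy
#' indicates a convex (quadratic) law.
#'
#' @param volumeMl cavity volume in mL.
#' @param energyJ deposited energy in J (> 0).
#' @return Ratio in mL/J. Vectorized.
#' @export
energyVolumeRatio <- function(volumeMl, energyJ) {
  if (any(energyJ <= 0)) stop("energy must be positive")
  volumeMl / energyJ
}
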