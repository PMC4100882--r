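# soapCT

Volumetric CT analysis of wound cavities in ballistic soap.

Ballistic (glycerin) soap is a plastic tissue simulant: unlike gelatin it
permanently retains the cavity that a bullet carves into it, so the
permanent cavity can be measured after the shot and used as a proxy for
potential wound damage. The classical way to quantify it — cut the block,
photograph it, delineate the cavity sparsely and stack truncated cones —
is destructive and assumes circular cross-sections. Imaging the intact
block with computed tomography instead gives a full 3D voxel model of the
cavity and of every metal fragment the bullet shed.

`soapCT` implements that volumetric workflow as a reusable, tested R
package, for terminal-ballistics researchers, wildlife-management
scientists comparing lead-free and lead-based hunting ammunition, and
forensic analysts:

- **Segmentation** — region growing of the soap block at a fixed relative
  threshold (50% of the estimated soap intensity), of the air-filled
  cavity within a slice range (or fully automatically), and of metal
  fragments above 2000 HU, with a geometric exclusion rule for small
  specks near large fragments that are likely CT streak artifacts.
- **Morphometry** — cavity volume *V* (mL); cross-sectional area profile
  *A(z)*; deflection angle θ = arccos |u⃗·v⃗| between the principal
  (PCA) axes of cavity and block; and the maximal inscribed sphere from a
  spacing-aware Euclidean distance transform, whose centre depth marks the
  depth of maximal damage.
- **Cutting-method model** — segment-wise truncated cones from sparse
  (depth, radius) delineations, V = Σ πh/3 (r₁² + r₁r₂ + r₂²), for
  comparison against CT.
- **Ballistics bookkeeping** — deposited energy
  E = ½ m_in v_in² − ½ m_exit v_exit², gram↔grain conversion, retained
  mass fractions, volume-to-energy ratios.
- **Statistics** — linear and quadratic least-squares fits through the
  origin, model selection by AIC = n ln(RSS/n) + 2k, ANCOVA on slopes,
  one-way ANOVA with Tukey's HSD, and Pearson correlations for
  reproducibility and method comparison.
- **Synthetic phantoms** — a generator that renders CT-like soap blocks
  (soap ≈ +100 HU, air ≈ −1000 HU, fragments ≈ +3000 HU) with parametric
  cavity families (tumbling spindle, early opening, tear shaped, cylinder,
  ellipsoid), fragments, streak artifacts and noise — with analytic ground
  truth, so every stage of the pipeline is validated end to end.

Volumes are read and written as NIfTI (`.nii`, `.nii.gz`) or MetaImage
(`.mha`, `.mhd`), with voxel spacing carried in the header.

## Worked example

Generate a phantom mimicking a tumbling (dimensionally stable) bullet —
a spindle-shaped cavity bulging at 160 mm depth, tilted 6° off the shot
line, with 3 metal fragments and streak artifacts — then analyze it:

```r
library(soapCT)
spec <- phantomSpec(blockShapeMm = c(120, 120, 260), voxelSpacingMm = 1,
                    cavityFamily = "tumbling_spindle",
                    cavityParams = list(max_radius_mm = 28, max_depth_mm = 160,
                                        length_mm = 220, width_mm = 36,
                                        tilt_deg = 6),
                    nFragments = 3L, streakArtifacts = TRUE,
                    noiseSdHu = 15, seed = 11L)
ph <- generatePhantom(spec)
ph$truth
#> PhantomTruth: volume 130.80 mL, tilt 6.00 deg, 3 fragments
#>   max sphere r = 27.99 mm at depth 159.1 mm

an <- analyzeShot(ph$volume,
                  shotMetadata = data.frame(bullet = "ILS",
                                            mass_initial_g = 8.45,
                                            speed_in_mps = 900,
                                            mass_exit_g = 8.4,
                                            speed_out_mps = 135))
an$metrics
#> CavityMetrics: 130.88 mL, deflection 6.22 deg, max sphere r 27.39 mm at depth 159.0 mm
an$fragments
#> FragmentSet: 5 fragments (3 counted)
an$record$deposited_energy_j
#> [1] 3345.705
```

The pipeline recovers the analytic cavity volume within 0.1% here, the
6° tilt within a quarter degree, and the inscribed-sphere radius and depth
within a voxel. Five components exceed the 2000 HU fragment threshold, but
two of them are single-voxel streak specks sitting within 5 mm of a large
fragment; the exclusion rule flags them, leaving the true count of 3.
The deposited energy follows from the masses and the entry/exit speeds:
½·0.00845·900² − ½·0.0084·135² ≈ 3346 J.

A whole synthetic study — 4 bullet types × 4 impact speeds × 2
repetitions = 32 blocks, volumes drawn from per-type volume–energy laws —
runs with

```r
report <- runStudy(studyConfig(seed = 1, outDir = "study_out"))
```

and produces per-shot metric and fragment tables (CSV) plus a study-level
JSON report with per-bullet through-origin fits and AIC choices, ANCOVA on
volume-to-energy ratios, ANOVA/Tukey on deflection angle and depth of
maximal damage, and first-vs-second-shot reproducibility correlations.
A thin command-line wrapper with `simulate` / `segment` / `analyze` /
`study` subcommands is installed at `inst/scripts/soapct`.

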