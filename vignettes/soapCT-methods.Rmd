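---
title: "soapCT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{soapCT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

A hunting bullet fired into a block of ballistic (glycerin) soap leaves a
permanent cavity whose size and shape summarize how the bullet released
its kinetic energy: a dimensionally stable bullet tumbles and bulges the
channel deep in the block, a tip-activated bullet opens early, and
deforming (mushrooming) bullets grow a tear-shaped cavity. CT imaging of
the intact block yields a voxel model of that cavity and of every metal
fragment, replacing the destructive cut-photograph-delineate workflow.
`soapCT` implements the full chain — segmentation, morphometry, the
legacy truncated-cone model, energy bookkeeping, and the statistical
comparisons across bullet types — together with a synthetic phantom
generator that provides analytic ground truth for validation.

# Segmentation model

All three segmentations are intensity-threshold rules on the Hounsfield
scale, as is appropriate for a three-material scene (air ≈ −1000 HU,
soap ≈ +100 HU, metal ≫ +1000 HU):

* **Soap intensity estimation.** The 50% rule needs a reference value.
  We use a two-class Otsu split of a 512-bin intensity histogram to
  separate air from denser material, then take the median of the upper
  class. The median is insensitive to the tiny metal tail, and the
  estimator is fully deterministic. On a noiseless phantom it returns the
  rendered soap value exactly.
* **Block.** All voxels at or above 0.5 × soap intensity, reduced to the
  largest 6-connected component. Fragments embedded in soap are part of
  the block; cavity air is below threshold and excluded by construction,
  so block and cavity masks partition.
* **Cavity.** Air voxels (< 0.5 × soap) enclosed by the block, grown with
  6-connectivity from automatically found seeds and restricted to a
  user-chosen axial slice range. Seeds are the air regions of the first
  slice that cannot be reached from the slice border — i.e. air enclosed
  by the block cross-section. The original interactive step thus reduces
  to two slice indices; a fully automatic mode (the default in
  `analyzeShot()`) instead takes the largest interior air component
  within the block's axial extent, which is well defined because the
  cavity communicates with outside air only through the entry face.
* **Fragments.** Connected components above a fixed 2000 HU threshold,
  using 26-connectivity (fragments can be single voxels touching
  diagonally). Components are relabelled deterministically by centroid
  (z, then y, then x).
* **Streak exclusion.** Dense metal causes streak artifacts that can
  masquerade as small fragments near large ones. A fragment with volume
  ≤ `smallMaxMm3` (default 8 mm³) whose distance to the nearest
  larger-than-small fragment is ≤ `proximityMm` (default 5 mm) is flagged
  `counted = FALSE` but kept in the table. Both constants are exposed
  because no canonical values exist; the counted number is non-increasing
  in the proximity radius and equals the raw component count at radius 0.

Connectivity choices (6 for block/cavity growing, 26 for fragments) are
standard practice; nothing in the workflow pins them down uniquely, so
they are fixed here and documented rather than configurable.

# Morphometry

* **Volume** is voxel count × voxel volume (mL). **Area profile** is the
  per-slice foreground count × in-plane voxel area, reported against
  depth in mm from the block entry face (scanner-independent, unlike
  slice indices).
* **Axes and deflection.** The principal axis of a mask is the leading
  eigenvector of the covariance of its unweighted voxel coordinates
  (the mask is binary; intensity weighting would be meaningless). The
  deflection angle uses arccos of the absolute dot product of the cavity
  and block axes, folding eigenvector sign ambiguity away and mapping
  antiparallel axes to 0°. When the two leading eigenvalues differ by
  less than a factor 1.5 the direction is ill-defined (a near-spherical
  mask); the axis is still returned but flagged degenerate with a
  warning.
* **Maximal inscribed sphere.** An exact Euclidean distance transform
  (Felzenszwalb–Huttenlocher lower-envelope algorithm, separable per
  axis, anisotropic-spacing aware) gives each cavity voxel its distance
  in mm to the nearest non-cavity voxel centre; the grid border counts as
  boundary. The maximum is the inscribed-sphere radius, its position the
  centre, and the centre's z the depth of maximal damage. Ties are broken
  towards the smallest z, then y, then x. Because distances are measured
  to voxel centres the radius carries a half-voxel-scale discretization
  error, which is why recovery tests use a one-voxel tolerance.

The transform and the connected-component/region-growing kernels are
compiled (Rcpp): no installed R package provides them in 3D, and the 10⁶-
to 10⁷-voxel grids make pure-R implementations impractical. The distance
transform is verified in the test suite against an exhaustive O(n·m)
distance computation on small random masks, and both exclusion-rule and
inscribed-sphere calls crop to padded bounding boxes, which is exact
(the pad layer is genuine background) and much faster.

# The cutting-method model

The legacy method models the cavity between successive delineations
(depth, radius) as truncated cones: V = Σ πh/3 (r₁² + r₁r₂ + r₂²), radius
linear in depth between knots — deliberately without smoothing, because
the frustum assumption *is* the model. `sampleCuttingKnots()` emulates
the manual delineation of a cut block: one measurement per 2 cm, each
radius taken as the local maximum of the silhouette around the click
(the delineator traces the visible cavity wall) with multiplicative
noise. Taking local maxima biases the recorded radii — and therefore the
cutting-method volume — upward relative to the CT voxel volume, which
reproduces the direction of the systematic disagreement between the two
methods; the package checks the direction, not a particular magnitude.

# Energy bookkeeping

Deposited energy is the kinetic-energy balance
E = ½ m_in v_in² − ½ m_exit v_exit² (masses in g converted to kg, speeds
in m/s, E in J). Multi-fragment exits are treated as one effective exit
mass and speed, matching what a single exit light barrier measures.
The grain is fixed at its exact avoirdupois definition, 0.06479891 g.

# Statistics

Volume-over-energy curves are fitted by least squares **through the
origin** (zero energy deposits zero volume), over the basis {x} or
{x, x²}, solving the normal equations directly. Two conventions are
declared because competing ones exist:

* **R²** is computed against the grand-mean baseline, 1 − RSS/TSS with
  TSS centred on ȳ. For through-origin fits this can be negative; it is
  comparable across the two candidate models, which is what matters here.
* **AIC** uses the least-squares form n·ln(RSS/n) + 2k with the error
  variance counted among the parameters (k = degree + 1). Only the
  difference between the linear and quadratic candidates is meaningful.
  A known property of this (standard) criterion: under a true linear law
  the quadratic candidate still wins whenever
  F(1, n−2) > (n−2)(e^{2/n} − 1), an event of probability ≈ 24% at n = 8
  and ≈ 16% asymptotically. AIC is efficient, not consistent; with the
  small per-bullet sample sizes typical of shot designs, a preference for
  the quadratic model is only strong evidence of curvature when the AIC
  difference is large. The test suite asserts the *exact* expected
  selection rate (via the F distribution) rather than pretending the
  criterion never overfits.

Slope comparisons use ANCOVA — the F-test of the group×slope interaction
in the pooled linear model, via `lm()`/`anova()`. Group comparisons of
deflection angle and depth of maximal damage use one-way ANOVA (`aov`)
with Tukey's HSD (`TukeyHSD`, studentized-range distribution).
Correlations are Pearson (`cor.test`). The significance level defaults to
α = 0.05 and is configurable. The suite checks both test families against
brute-force permutation oracles on micro-datasets and verifies type-I
calibration under null simulations.

# The phantom generator

A phantom is defined by a `PhantomSpec`: block extents (default
250 × 250 × 400 mm — typical soap-block proportions with the long axis as
the shot axis; the true dimensions of any given laboratory's blocks vary,
so everything is configurable), voxel spacing (default 1 mm isotropic),
rendering intensities (soap +100 HU, air −1000 HU, fragments +3000 HU —
chosen so both threshold rules hold with wide margins), a cavity family,
fragments, streaks and Gaussian noise (default 15 HU, the magnitude of a
clinical medium-sharp reconstruction).

Cavities are **surfaces of revolution** around an axis through the centre
of the entry face, tilted by `tilt_deg` about the y axis. Each family is
a piecewise-smooth radius profile r(d) on [0, L]:

* `tumbling_spindle` — narrow entry channel (neck, default 4 mm) plus a
  Gaussian bulge peaking at `max_depth_mm` (a tumbling bullet's bulge,
  around 200 mm for the brass bullet class);
* `early_opening` — rises to near-maximal radius within the first
  quarter of the track, then tapers (tip-activated expansion);
* `tear_shaped` — a beta-shaped bulge, smooth rise then taper
  (deforming bullets);
* `cylinder` and `ellipsoid` — analytic solids for oracle tests.

The analytic volume is π∫r(d)²dd (quadrature at 10⁻⁹ relative
tolerance), and the true maximal inscribed sphere is found by a 1D search
over axis positions against the profile curve and the two end planes —
both independent of the voxel renderer, so voxelization and segmentation
errors are measured against genuinely external truth. Fragments are
spheres placed in the soap just outside the cavity wall; streak artifacts
are 1-voxel-thick radial spokes alternating ±500 HU within 5 mm of
fragments whose radius is above the median, plus single-voxel specks at
fragment intensity in the same band — enough to exercise the exclusion
rule, deliberately not a physics model of beam hardening. Generation is
bit-reproducible for a fixed seed and restores the caller's RNG state.

What the phantom does **not** emulate: partial-volume blur at the
soap/air interface, beam hardening and scatter, anisotropic reconstruction
kernels, cavity wall roughness and fissures, and non-circular
cross-sections (real tumbling cavities are notably elliptical where the
bullet travels sideways). Passing the recovery suite therefore shows the
pipeline is correct on geometrically clean inputs with realistic contrast
and noise, not that segmentation thresholds are optimal for any
particular scanner.

# The synthetic study

`runStudy()` mirrors the experimental design: 4 bullet types × 4 impact
speeds × 2 repetitions = 32 blocks (16 configurations). Impact speeds are
600–900 m/s for the light brass bullet, 550–850 m/s for the two copper
bullets and 500–800 m/s for the heaviest, lead-core bullet. Exit masses
scale with the catalogue's maximal exit fractions (99.4 / 64.9 / 73.6 /
54.7% for ILS / TAG / TSX / NVU) times (v/v_max)², with exit speed 0.15 v;
deposited energy then follows from the balance. Cavity volumes are drawn
from per-type volume–energy laws — linear (0.10 mL/J) for the
dimensionally stable and fragmenting types, quadratic
(0.04 mL/J + 2.5·10⁻⁵ mL/J²) for the deforming types — with 5%
multiplicative shot-to-shot noise, and the family's maximal radius is
solved by `uniroot` so the analytic cavity volume hits the target.
Tilt draws centre on 6° for the tumbling type and 1.5° for the others;
fragment counts grow linearly with deposited energy (none for brass, most
for the lead-core type). These constants are the generator's definition
of a realistic study, chosen once; the laws were scaled so that every
target volume stays below the feasible cavity size of the study block
(capping a target would flatten the law's top end and distort the model
comparison).

Study runs use 150 × 150 × 300 mm blocks at 2 mm voxels and the recovery
suite uses ~100 × 100 × 200 mm blocks at 1 mm — sizes chosen so the full
suite exercises millions of voxels per block while a complete study runs
in well under a minute. All statistics in the report are computed from
the *measured* (segmented) quantities, never from the generating targets.

# Degenerate inputs and error contracts

Constant-intensity volumes are rejected by the soap estimator; an all-air
volume raises "no block found"; an intact block raises "no cavity found";
an empty fragment set is a valid result, not an error. Masks constructed
against a declared parent volume must match its grid exactly. MetaImage
files without an `ElementSpacing` are rejected rather than defaulted;
truncated files are detected by payload size. In `runStudy()` any stage
failure aborts with the shot id, bullet, speed and repetition in the
error message.

# Known limitations

* The voxelization error of small cavities oscillates with the lattice
  alignment rather than decreasing smoothly; sub-voxel partial-volume
  modelling is out of scope.
* The deflection angle is a single rigid-axis summary; strongly curved
  trajectories would need a centreline model.
* The cutting-method comparison uses knots sampled from the *parametric*
  silhouette; delineating rendered photographs (with perspective) is not
  modelled.
* Only the permanent cavity is analyzed; temporary-cavity dynamics are
  invisible to post-hoc CT of soap.
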