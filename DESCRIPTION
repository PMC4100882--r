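Package: soapCT
Title: Volumetric CT Analysis of Wound Cavities in Ballistic Soap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of permanent wound cavities created by
    hunting bullets in ballistic soap blocks imaged with computed tomography.
    Provides threshold-based region-growing segmentation of the soap block,
    the air-filled cavity and metallic fragments (with a geometric exclusion
    rule for streak-artifact specks), cavity morphometry (volume,
    cross-sectional area profile, deflection angle from principal component
    analysis, and depth of maximal damage via the maximal inscribed sphere of
    an anisotropic Euclidean distance transform), the segment-wise
    truncated-cone model underlying the legacy cutting method, deposited-energy
    bookkeeping from entry/exit speeds and masses, and the statistical layer
    used to compare bullet types (through-origin linear and quadratic fits with
    AIC model selection, ANCOVA on slopes, one-way ANOVA with Tukey HSD, and
    Pearson correlations). A synthetic phantom generator renders CT-like soap
    blocks with parametric cavities, metal fragments, streak artifacts and
    noise, with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
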