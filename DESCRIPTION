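Package: strokevol
Title: Diameter-Based Estimation of Ischemic Lesion Volume on DWI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rapid diameter-based estimation of acute ischemic stroke lesion
    volume from binary DWI lesion masks. Implements slice selection by largest
    lesion extent, maximum Feret and maximal orthogonal caliper diameters on
    anisotropic pixel grids, the od-value (a x b) score with its volume
    polynomial and the 32/42 cutoffs for >70 ml and >100 ml infarcts, the
    ABC/2 ellipsoid approximation, gold-standard voxel volumetry, and the
    diagnostic-accuracy evaluation comparing the estimators (sensitivity,
    specificity, accuracy, PPV, NPV with exact binomial confidence intervals,
    rank-based C-statistic, percent overestimation of median volume).
    Includes a synthetic 3D lesion-phantom cohort generator with known
    analytic ground truth, and a confusion-matrix reconstructor that recovers
    integer 2x2 tables from published cohort marginals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
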