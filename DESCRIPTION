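Package: petrep
Title: Test-Retest Repeatability of PET Radiomics Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lesion-level test-retest repeatability analysis for quantitative
    PET imaging biomarkers. Provides a synthetic paired-phantom generator with
    known within-subject variability and intertracer bias, SUV-based lesion
    segmentation and isotropic resampling, conventional SUV/volume metrics, a
    107-feature IBSI-aligned radiomics catalogue with a 16-filter image bank
    (intensity transforms, Laplacian of Gaussian, undecimated wavelets), and
    repeatability statistics: within-subject coefficient of variation,
    repeatability coefficient, Bland-Altman limits of agreement, two-way
    mixed-effects absolute-agreement intraclass correlation with exact
    F-based confidence intervals, and confidence-bound reliability
    classification. Includes cohort-level orchestration, filter-effect
    testing and volume-redundancy screening.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
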