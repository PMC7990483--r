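Package: ccistrain
Title: Controlled Cortical Impact Biomechanics and Strain-Based Injury Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a controlled cortical impact (CCI) on a voxel-based
    rat-brain phantom with an explicit-dynamics hyper-viscoelastic finite
    element solver (Ogden deviatoric hyperelasticity with Prony-series shear
    relaxation), reduces the deformation histories to per-element maxima of
    first principal Green-Lagrange strain and strain rate, summarises them
    over corpus-callosum segments and threshold-exceedance volume fractions,
    and relates them to synthetic imaging and histology outcomes through
    linear mixed-effects models with marginal and leave-one-animal-out
    predictive R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    lme4,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
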