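Package: melapress
Title: Quantification Pipeline for Intermittent-Compression Melanoma Culture Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based and molecular quantification for cell-culture
    compression experiments: digital image correlation (DIC) strain mapping of
    microsphere-seeded collagen gels, Green-Lagrange strain fields, creep-curve
    fitting with the three-element generalized Kelvin-Voigt model, colony
    progression distance and rate, live/dead cell counting, skeletonization-based
    F-actin filament length, 2^-ddCt relative expression, and Dunnett many-to-one
    testing. Includes seeded synthetic-data generators with known ground truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    mvtnorm,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
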