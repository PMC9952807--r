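Package: strainavoid
Title: Strain-Avoidance Modelling of Cardiac Cell Alignment in Grooved
    Stretch Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation and analysis toolkit for predicting the
    preferred orientation of cardiac cells cultured in grooved elastomer
    chambers under cyclic uniaxial stretch. Builds parametric grooved-chamber
    geometries and tagged hexahedral meshes, solves static linear elasticity
    for applied-stretch and cellular self-condensation (eigenstrain) load
    cases with elastic-spring sidewall support, and combines the two
    directional stress-fiber elongation fields through a nonlinear
    strain-avoidance addition law to predict alignment angles, including
    oblique angles reminiscent of the helicoidal fiber layout of the
    myocardium. Also provides synthetic-data generators and quantification
    for fluorescence-style cell images (structure-tensor orientation
    distributions, marker area fractions) and beating time-lapse videos
    (block-wise local frequency and phase maps via temporal peak detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
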