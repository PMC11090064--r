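Package: ridens
Title: Mass Density Estimation from Refractive Index Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the mass density of complex biological mixtures from
    refractive index (RI) measurements, as obtained e.g. by optical
    diffraction tomography or quantitative phase imaging. Implements the
    Biot and Lorentz-Lorenz RI mixing rules under volume additivity,
    effective RI-increment/partial-specific-volume parameters for
    multi-component solutes, closed-form Gaussian propagation of
    uncertainty, a voxel/voxelino Monte-Carlo simulator of correlative
    (density, RI-contrast) distributions, sequence-based protein RI
    increments and partial specific volumes from amino-acid composition,
    and weighted fitting of refractometry/pycnometry concentration series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
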