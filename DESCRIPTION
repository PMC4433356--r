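Package: spectex
Title: Tree-Species Classification from Multispectral Imagery with
    Spectral-Spatial Texture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for supervised tree-species
    classification in high-spatial-resolution multispectral satellite
    imagery. Covers radiometric calibration of digital numbers to
    at-sensor radiance and dark-object surface reflectance, principal
    component substitution pansharpening, vegetation-index expansion
    (NDVI, SAVI, EVI, ARVI, VARI), Lee-sigma spectral-spatial texture
    filtering, Gaussian signature training with transformed-divergence
    separability, pixel classifiers (maximum likelihood, Mahalanobis
    distance, spectral angle mapper, spectral information divergence),
    kappa-based accuracy assessment, accuracy-improvement-efficiency
    statistics with two-way factorial ANOVA and Duncan's multiple range
    grouping, and a seeded synthetic canopy-scene generator for testing
    the full pipeline without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
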