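Package: swirauth
Title: Non-Targeted Authentication of Powdered Foods from Shortwave-Infrared
    Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and chemometric analysis of shortwave-infrared (SWIR,
    900-2494 nm) hyperspectral images of powdered food mixtures, built around
    the almond-powder adulteration screening problem. Provides a synthetic
    plate-image generator (endmember spectra, linear mixing, scatter and
    sensor noise, dark/white references), reflectance calibration, background
    segmentation and well-spectrum extraction, the standard spectral
    pretreatments (normalizations, SNV, MSC, Savitzky-Golay derivatives), a
    data-driven SIMCA (DD-SIMCA) one-class classifier with chi-square
    acceptance and outlier boundaries, NIPALS PLS1 regression of adulterant
    concentration with leave-one-out factor selection, per-pixel chemical
    concentration mapping, classification and design-statistics metrics, and a
    config-driven end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
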