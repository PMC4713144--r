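Package: thrombodens
Title: Entire-Thrombus Density Measurement on Paired CTA/NCCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated measurement of the complete Hounsfield-unit density
    distribution of intracranial thrombi in acute ischemic stroke from paired
    CT angiography (CTA) and non-contrast CT (NCCT) volumes. Implements
    seed-based segmentation of the contralateral artery, midsagittal
    mirror-symmetry mapping onto the occluded side, intensity-based thrombus
    region growing, rigid mutual-information CTA-to-NCCT registration,
    whole-thrombus density-distribution descriptors (median, IQR, skewness,
    kurtosis, volume), a simulated three-ROI manual measurement with a
    configurable hyperdense-seeking observer-bias model, and the full
    observer-agreement toolbox (Bland-Altman, intraclass correlation, paired
    t-tests, ordinary least squares, Kruskal-Wallis). Ships a synthetic
    phantom generator producing paired CTA/NCCT head phantoms with known
    thrombus density distributions, noise, partial-volume blur and a known
    rigid misalignment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
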