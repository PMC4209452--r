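Package: biofluo
Title: Simulation and Analysis Chain for Integrated SPECT, Bioluminescence
    and Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Anna", "Verhoeven", email = "anna.verhoeven@example.org",
           role = c("aut", "cre"))
Description: Digital-phantom simulation and processing pipeline for a
    combined planar optical (bioluminescence/fluorescence) and SPECT
    small-animal imaging platform. Provides a parametric tissue-gel
    phantom with an obliquely inserted capillary source, CCD image
    formation with realistic noise, flat-field illumination correction,
    hot-pixel median filtering, list-mode gamma event simulation,
    triple-energy-window scatter correction, OSEM reconstruction with
    Gaussian post-filtering, thresholded color overlays with contour-based
    registration, and quantitative depth, attenuation and resolution
    characterization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
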