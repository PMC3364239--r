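Package: fpfa
Title: Fluorescence Polarization and Fluctuation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of polarization-resolved time-correlated single photon
    counting (TCSPC) data by Fluorescence Polarization and Fluctuation Analysis
    (FPFA): time-resolved fluorescence anisotropy and lifetime decays from photon
    micro-times (homo-FRET detection), multi-tau auto-/cross-correlation of photon
    macro-times with single-component two-photon 3-D Gaussian diffusion fits,
    molecular and normalized brightness for subunit stoichiometry, beam-geometry
    and g-factor calibration, concentration bookkeeping, background-brightness
    corrections, and the binomial donor-fraction pairing model for hetero-FRET.
    Includes a Brownian-dynamics photon-stream simulator with full ground truth so
    every stage can be validated without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
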