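Package: dermamc
Title: Monte Carlo Photon Transport in Layered Skin for Transcutaneous
    Optical Power Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: MCML-style Monte Carlo simulation of near-infrared light
    propagation through a four-layer skin model (epidermis, dermis, fat,
    muscle), driven by an incoherent LED source with a Gaussian spectral
    model. Computes specular and diffuse reflectance, per-layer absorbed
    fractions, cylindrical r-z energy-density maps, depth-resolved
    crossing energy, detector capture fractions, an ICNIRP irradiance
    safety check, and recoverable photovoltaic power estimates for
    optically recharged implantable biosensors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
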