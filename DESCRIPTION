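Package: envdose
Title: Organ Equivalent Dose Rate Coefficients for External Environmental
    Exposure of the Pregnant Female and Fetus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes radionuclide-specific organ equivalent dose rate
    coefficients for external exposure to environmental photon sources:
    ground contamination (an infinite plane source buried at 0.5 g/cm2 in
    soil) and submersion in a semi-infinite radioactive cloud.  Packages
    monoenergetic fetal organ and air-kerma coefficient tables, interpolates
    them with a monotone piecewise cubic Hermite scheme in log-energy space,
    and folds them with radionuclide decay emissions (discrete photon lines,
    continuous beta spectra, and electron emissions mediated by a
    thick-target bremsstrahlung kernel).  Also provides a simplified analog
    photon Monte Carlo of the air-over-soil environment that records
    phase-space probability density functions on a coupling cylinder and
    estimates air kerma free-in-air at 1 m height.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
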