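Package: uhdrdosim
Title: Ultrahigh-Dose-Rate Proton Dosimetry with Ion Chambers and Graphite
    Calorimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for reference dosimetry of ultrahigh-dose-rate
    (FLASH) pencil-beam-scanning proton fields. Determines ion-recombination
    correction factors for plane-parallel ionization chambers from
    charge-versus-voltage saturation curves by four methods (two-voltage
    technique, linear and three-voltage linear extrapolation, Niatel quadratic
    model, and a semiempirical model with an exponential charge-multiplication
    term), converts corrected chamber charge to absorbed dose to water
    following the TRS-398 formalism, derives dose to water from
    quasi-adiabatic graphite-calorimeter temperature traces, and compares
    chamber and calorimeter doses field by field with combined uncertainties.
    A seeded synthetic-data generator emulates complete measurement campaigns
    so every stage is testable without access to experimental raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
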