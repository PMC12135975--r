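Package: crystkin
Title: Multi-Technique Kinetic Analysis of Salt-Induced Protein Crystallization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for following salt-induced protein
    crystallization across complementary experimental probes: logistic
    (sigmoid) kinetic modelling shared by all techniques, dynamic light
    scattering double-exponential decomposition with Fickian Gamma = D q^2
    extraction, neutron spin echo intermediate scattering functions with an
    immobile crystal fraction at the Bragg position, neutron backscattering
    fixed-window-scan ratio analysis with elastic-fraction extraction,
    in situ diffraction Bragg-peak crystal-fraction estimation, and
    per-crystal microscopy area kinetics.  Every stage is paired with a
    seeded synthetic-data generator so that the complete chain is testable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    readr,
    withr
Config/testthat/edition: 3
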