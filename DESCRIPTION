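Package: ringforce
Title: Contractile Force of the Actomyosin Ring During Epithelial Cell Extrusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the contractile pressure of the actomyosin ring that
    drives apoptotic cell extrusion from embryonic epithelia, from fluorescence
    time-lapse measurement of ring size through laser-energy to impulsive-force
    calibration, the counter-balance regression of squared ring radius on total
    force, and conversion of the fitted slope to a pressure under a spherical
    volume-wave propagation model.  Includes a synthetic-data module that
    emulates the calibration tables, annulus time-lapse movies and
    counter-balance observation sets the analysis consumes, with ground-truth
    records for recovery testing, plus condition comparison by one-tailed
    Student's t-test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
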