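Package: gaitbattery
Title: Digital Gait Characteristic Battery and PLS-DA Classification from
    Lumbar Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of a 210-characteristic digital gait battery
    (spatiotemporal, frequency, regularity, magnitude and complexity
    domains) from lower-back tri-axial accelerometry segmented by gait
    events, together with a from-scratch partial least squares
    discriminant analysis (PLS-DA) classifier with cross-validated
    component selection and variable-importance-in-projection (VIP)
    ranking.  Includes a synthetic cohort generator emulating a
    two-minute oval-circuit walking protocol with instrumented-mat
    passes, so the whole pipeline is testable end to end without any
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    mixOmics,
    optparse,
    yaml
Config/testthat/edition: 3
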