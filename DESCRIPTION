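Package: firesync
Title: Fire-Scar Chronologies and Fire-Climate Synchrony Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and analysing multi-century fire
    histories from crossdated fire-scar records. Reads and writes the FHX
    (Fire History Exchange) text format, builds composite fire chronologies
    with a two-tree event rule and post-fire cohort verification, and
    computes mean and point fire intervals. Relates fire years to
    reconstructed climate indices (PDSI, ENSO, PDO, AO) through extreme-event
    sets, a one-dimensional bivariate Ripley's K with Monte Carlo confidence
    envelopes, and G-tests of fire frequency across climate phases, and
    models the spatial pattern of burning with Poisson generalized linear
    models ranked by AICc with Akaike-weight model averaging. A synthetic
    landscape and fire-regime generator with known ground truth supports
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
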