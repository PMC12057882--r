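Package: oasisrisk
Title: Landscape Ecological Risk Assessment for Oasis-Desert Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing landscape ecological risk in arid oasis-desert
    regions. Classifies NDVI imagery into oasis, transition and desert belts,
    computes a composite ecological risk index (ERI) from landscape
    fragmentation, separation, dominance, disturbance and fragility on a
    square sampling grid, quantifies spatial clustering of risk with global
    and local Moran statistics (LISA cluster typing), accounts for land-use
    transitions and projects class areas with a Markov chain under natural
    and policy-intervention scenarios, and ranks risk drivers with an
    out-of-bag permutation importance harness around a random-forest
    regression. Includes a synthetic-landscape generator so the full pipeline
    runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
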