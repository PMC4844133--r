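Package: solnet
Title: Network Autoregression of National Outcomes on Socio-Linguistic and Spatial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether political and economic change among nation
    states patterns on socio-linguistic affiliation networks versus spatial
    networks. Builds pairwise weight matrices from language-divergence and
    geographic distances (distance-derived affinities, row-normalized
    adjacencies), fits the Gaussian linear network-disturbances
    autoregression with up to four simultaneous weight matrices by maximum
    likelihood, runs exhaustive BIC model-selection sweeps over time-binned
    outcome panels with Bayes-factor reporting, single-matrix significance
    censuses, and a trait-diffusion simulation study, and generates synthetic
    worlds (toy phylogenies, coordinates, outcome panels) with known ground
    truth so every stage runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
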