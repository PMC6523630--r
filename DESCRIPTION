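Package: lipidrules
Title: Rule-Based Lipid ESI-MS/MS Spectral Prediction and Metadata-Weighted
    Compound Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts electrospray-ionization tandem mass spectra (ESI-MS/MS)
    of modular lipids from class- and adduct-specific fragmentation rules at
    collision energies of 10, 20 and 40 eV, with categorical peak intensities.
    Provides elemental-formula arithmetic, monoisotopic mass and adduct m/z
    computation, lipid shorthand parsing, peak-list and MSP spectrum I/O,
    cosine (dot-product) spectral similarity with tolerance-based peak
    alignment, and a spectral-library search that combines spectral similarity
    with literature-citation counts and chemical-ontology class frequencies
    into a single weighted candidate score. Includes deterministic synthetic
    library and identification-challenge generators, ranking evaluation
    metrics (top-k, medal score), chemical-class prediction, grid-search
    weight optimization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
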