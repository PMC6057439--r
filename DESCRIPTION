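Package: tendonmech
Title: Tensile Mechanics and Collagen Fibril Morphometry of Tendon Fascicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving tensile mechanical properties of tendon
    fascicles from raw load-displacement traces (zeroing of the slack region,
    stress-strain conversion, polynomial-smoothed yield-point location,
    trapezium-rule strain energy densities) and for collagen fibril
    morphometry from transmission electron microscopy measurements
    (equivalent-circle diameters, fibril area fractions, diameter-frequency
    histograms, and bimodal subpopulation decomposition by simulated
    annealing with Metropolis acceptance and non-negative least-squares
    amplitude fitting). Includes add-in-quadrature measurement-uncertainty
    propagation, Welch two-sample power analysis, and ground-truthed
    synthetic-data generators for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
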