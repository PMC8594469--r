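Package: rnatraffic
Title: Quantification of Single-Molecule mRNA Transport and Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify motor-driven mRNA transport in live-cell
    fluorescence microscopy: Laplacian-of-Gaussian spot detection with
    sub-pixel localization, nearest-neighbour spot linking, per-track motion
    metrics (displacement, linearity of forward progression, mean speed,
    mean square displacement, velocity autocorrelation), threshold-based
    classification of directed versus diffusive tracks, the Peripheral
    Distribution Index of RNA signal relative to the nucleus, intensity-based
    calling of multimeric RNA clusters, and two-colour motor/mRNA cotransport
    analysis with kymographs. Includes a seeded synthetic-data generator that
    emulates the imaging conditions the analysis assumes (Brownian and
    directed particle populations, cytoskeletal drug perturbations, cell and
    nucleus geometries, and rendered image stacks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
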