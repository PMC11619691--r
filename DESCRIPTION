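Package: hcquant
Title: Quantification of Connexin Hemichannel Assays and Antibody Binding Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying connexin hemichannel activity from
    fluorescence and luminescence recordings and for post-processing
    alchemical free-energy calculations of antibody binding. Covers
    GCaMP calcium-imaging trace preprocessing (background subtraction,
    photobleaching correction, dF/dFmax normalization, peak and
    oscillation statistics), hemichannel assay statistics (cytosolic
    calcium load, DAPI uptake rate, ATP release, qPCR fold change,
    Hill dose-response fits), trajectory contact and RMSD analysis,
    Bennett acceptance ratio and exponential free-energy estimators
    with thermodynamic-cycle aggregation, a normality-gated group
    comparison tree, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    pracma,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
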