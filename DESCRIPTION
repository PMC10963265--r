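Package: poreCas9
Title: Decoding dCas9 Binding on Barcoded DNA Carriers in Solid-State Nanopores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of solid-state nanopore recordings of
    barcoded linear DNA nanostructures carrying dCas9-targetable dsDNA
    overhangs. Provides a phenomenological current-trace simulator with
    ground-truth logs (square-pulse blockades, five-spike barcodes,
    protein spikes, folded events, knot artifacts), a translocation event
    finder with noise and fold filters, orientation-aware barcode decoding
    and per-overhang binding calls, a sequence-level guide/target model
    (PAM finding, mismatch profiling, wobble classification, configurable
    position-dependent binding probabilities), and estimators for binding
    specificity, relative concentration, position-wise mismatch tolerance
    and binding efficiency with Wilson confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    rhdf5,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'barcodeDecode.R'
    'eventDetect.R'
    'guideModel.R'
    'io.R'
    'pipeline.R'
    'poreCas9-package.R'
    'quantify.R'
    'traceSim.R'
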