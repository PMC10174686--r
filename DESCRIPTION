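Package: behavex
Title: Behavioral Transcriptomics of Regenerating Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Live-imaging-guided single-cell analysis of airway epithelial
    regeneration. Quantifies tissue motion from time-lapse stacks
    (basement-membrane flattening, multi-pass particle image velocimetry,
    speed and directionality statistics, mover/non-mover classification,
    division-axis geometry), estimates ciliary beat frequency by Welch
    spectral analysis, and links behavior classes to transcriptomic
    signatures: quality control, detection-deviance variable-gene selection,
    marker-guided hierarchical clustering, two-part hurdle differential
    expression with likelihood-ratio tests, background-matched signature
    scoring, and shared-nearest-neighbor clustering. A synthetic-data module
    generates image stacks and count matrices with planted ground truth so
    the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rtsne,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    methods,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
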