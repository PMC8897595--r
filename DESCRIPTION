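Package: majsat
Title: Major-Satellite miRNA Targeting and Pericentromeric Foci Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for the computational analyses linking
    Argonaute-bound miRNAs to mouse pericentromeric heterochromatin:
    selection of long major-satellite regions from RepeatMasker
    annotations, miRNA seed-site (8mer) scanning and ranking over
    satellite sequences, AGO-loading enrichment classification from
    RIP/input small-RNA count tables, qPCR percent-input and
    2^-ddCt enrichment arithmetic, and a CellProfiler-style
    quantification chain for chromocenter/marker foci colocalization in
    two-channel nuclear images, with Mann-Whitney group comparison.
    Includes a synthetic-data module that generates every input with
    exact ground truth so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    EBImage,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
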