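Package: mosaicSV
Title: Somatic Structural Variant Concordance and Transposable-Element
    Analysis for Single-Cell Long-Read Callsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of somatic structural variants (SVs) called from
    whole-genome-amplified single cells and matched bulk tissue sequenced
    with long reads. Implements call-level quality and chimera filtering,
    single-cell versus bulk concordance and allelic-dropout accounting,
    transposable-element (SINE/Alu, LINE/L1) classification of variant
    sequences including detection of NAHR-mediated deletions flanked by
    same-family repeat pairs and insertion-site family preference, and
    permutation-based enrichment/depletion statistics with interval
    shuffling. Ships a synthetic-data generator that plants ground-truth
    germline and mosaic events (NAHR deletions, family-biased TE
    insertions, amplification chimera artifacts, allelic dropout) so the
    whole pipeline can be exercised end to end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
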