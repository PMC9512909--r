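Package: fragmetrics
Title: Stochastic DNA Fragmentation Modelling and the Fragment Calculator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models stochastic DNA fragmentation in clinical samples
    (sonicated, bisulfite-converted, FFPE and cell-free DNA). Implements the
    closed-form relationship between a sample's fragment-size distribution and
    the proportion of intact (PCR-amplifiable) copies of a region of any
    length, differential amplicon-length ratios, and mass-to-genome-copies
    conversion. The Fragment Calculator estimates total genome copies, average
    fragment length and intact copies at any region length from a short/long
    amplicon assay pair by interpolation against reference fragment-size
    profiles. Also provides a Monte Carlo fragmentation simulator, nucleosome
    Windowed Protection Score computation and peak calling for cfDNA fragment
    intervals, copy-number-neutral region filtering, cytosine-free priming-site
    scanning for bisulfite-compatible assay placement, and assay-level
    quantitation helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    Biostrings
Config/testthat/edition: 3
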