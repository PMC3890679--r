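Package: barcodekit
Title: Distance-Based DNA Barcoding Analysis for Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how well short standardized DNA barcodes
    (such as the plastid regions rbcLa and matK) discriminate plant species
    and assign unknown, often degraded, specimens to species. Implements
    Kimura two-parameter and p-distances with pairwise deletion, barcode-gap
    summaries and Wilcoxon comparisons of intra- versus interspecific
    divergence, distance-threshold optimization, three leave-one-out
    identification estimators (near neighbour, best close match, and
    fixed-cutoff BOLD-style identification), percent-identity matching of
    query sequences against a reference library with vernacular-name
    adjudication, neighbour-joining trees with column bootstrap and query
    placement, and a synthetic-library generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
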