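Package: barcodegap
Title: DNA Barcode Species Delimitation by Distance Summaries, Barcode Gap
    and Threshold Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for COI DNA-barcode surveys of
    animal communities: sequence quality control (length, ambiguity and
    reading-frame checks), Kimura 2-parameter distances with pairwise
    deletion, intraspecific/intrageneric/intrafamilial distance summaries,
    per-species barcode-gap and nearest-neighbor analysis, single-linkage
    OTU clustering with concordance classes against morphospecies labels,
    neighbor-joining trees with nonparametric bootstrap support, and
    rule-based candidate/cryptic species flagging. Includes a seedable
    barcode simulator under the Kimura two-parameter substitution process
    so every stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
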