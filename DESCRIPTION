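Package: mslineage
Title: Cell Lineage Reconstruction from Somatic Microsatellite Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective cell lineage analysis from microsatellite (MS)
    fragment-size genotypes of single cells and whole colonic crypts.
    Implements a symmetric stepwise mutation model (single and double repeat
    steps), maximum-likelihood estimation of the number of cell divisions
    separating two genomic signatures, neighbor-joining lineage trees rooted
    at a tail-derived zygote signature, per-cell depth and crypt
    most-recent-common-stem-cell (MRCSC) inference, hypergeometric clade
    enrichment tests with FDR control, depth summary statistics and
    mutation-rate calibration, and a simulator of colon crypt stem-cell
    dynamics under immortal-strand, asymmetric-division-only and monoclonal
    conversion scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
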