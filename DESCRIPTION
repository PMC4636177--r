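Package: moleimprint
Title: Genome-Wide Screen for Imprinting Defects in Hydatidiform Mole Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for detecting germline imprinting defects in
    hydatidiform moles from Infinium-style methylation-array beta values.
    Implements probe-level quality filtering, empirical-Bayes moderated
    two-group differential methylation on the beta scale, run-based
    candidate differentially-methylated-region (DMR) detection, and
    classification of each region's germline epigenotype from its
    methylation profile across androgenetic-mole, NLRP7-mutated-mole,
    normal-placenta, somatic and sperm sample groups. Also provides
    interpreters for orthogonal validation assays (bisulfite clone panels,
    methylation-sensitive HpaII genotyping, pyrosequencing outlier
    summaries, allelic-signal calls) and a seeded synthetic-data generator
    so the whole screen runs end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
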