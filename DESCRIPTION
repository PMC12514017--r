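Package: protectomap
Title: Imaging Transcriptomics of Sex Differences in Regional Cortical Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking sex differences in regional cortical
    atrophy to regional gene expression. Provides empirical-Bayes multi-site
    harmonization of parcellated cortical thickness (ComBat), control-referenced
    normative W-scoring, per-region sex-interaction estimation, partial least
    squares imaging transcriptomics with spatial-autocorrelation-preserving
    spin permutations and bootstrap gene ratios, preranked gene set enrichment
    with permutation NES/FDR and weighted set-cover redundancy reduction, and
    brain-versus-peripheral tissue enrichment of candidate genes. A synthetic
    data generator emulates the multi-site cohort, donor-level microarray
    bundles, and tissue expression tables, so the whole pipeline is testable
    without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    sva,
    fgsea,
    optparse
Config/testthat/edition: 3
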