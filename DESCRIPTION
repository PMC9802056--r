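Package: assemblytrace
Title: Reconstructing Lake Microbial Community Assembly from Upstream
    Sources with Paired 16S rDNA/rRNA Amplicon Tables
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to trace how a downstream (lake) bacterial community
    assembles from upstream source habitats along a river - vegetated
    habitat - lake continuum, using paired 16S rRNA gene (DNA) and
    transcript (RNA, sequenced as cDNA) OTU count tables. Implements
    repeated rarefaction with mean tables, per-OTU RNA:DNA activity
    ratios with sentinel handling and phantom-taxon exclusion, source
    attribution along the habitat continuum, dominance-tier and
    ten-fold abundance-shift classification, active/inactive/seed state
    calling, cross-campaign aggregation with rank-based copy-number
    tests, and a synthetic paired-table generator with planted,
    recoverable ground truth for every classification.
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
    vegan,
    withr
Config/testthat/edition: 3
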