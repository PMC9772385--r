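Package: editome
Title: A-to-I Editome Analysis for Early Embryonic Development
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing an adenosine-to-inosine (A-to-I)
    RNA editome across staged single-cell and bulk embryonic RNA-seq cohorts.
    Starting from per-sample candidate variant tables, the package filters
    candidate edits against known genomic variants and Alu-aware read-support
    rules, annotates genomic region and protein recoding effects, calls
    Recurrent Embryonic Edits (REEs) and REE-targeted genes per developmental
    stage, tracks REE persistence across stage transitions, scans for
    condition-specific complete loss of REEs in abnormal embryo groups,
    classifies the effect of each edit on microRNA binding sites (gain, loss,
    unchanged, mixed) from seed-match predictions on unedited and edited
    3'-UTRs, annotates maternal genes and targets of maternal mRNA clearance
    from expression medians, and runs the associated rank-based enrichment
    statistics. A deterministic synthetic-cohort generator with a ground-truth
    manifest makes every stage of the pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
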