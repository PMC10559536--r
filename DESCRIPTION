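Package: ernalink
Title: Enhancer Activity, Enhancer RNA and eQTL Linking in Stimulated Monocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative regulatory-genomics workflow for innate immune
    activation studies: consensus (recurrent) ATAC-seq peak construction
    across samples, simplified negative-binomial differential count testing
    with donor adjustment, promoter-proximal versus distal peak annotation
    with binned evolutionary-conservation profiles, enhancer-RNA (eRNA)
    definition and quantification from distal open chromatin, and
    eQTL-based enhancer-to-gene linking with a context-specificity
    enrichment test. Ships a seeded synthetic-data generator emulating a
    six-donor by five-condition stimulation design so the full pipeline is
    testable end to end without managed-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    MASS,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
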