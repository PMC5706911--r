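Package: ctlnc
Title: Cancer-Testis lncRNA Discovery and Functional Annotation
Version: 0.1.0
Authors@R:
    person("ctlnc", "maintainers", email = "ctlnc@example.org", role = c("aut", "cre"))
Description: Identifies testis-specific long non-coding RNAs (TS-lncRNAs)
    from a multi-tissue normal expression panel, calls cancer-testis
    lncRNAs (CT-lncRNAs) and extremely highly expressed CT-lncRNAs
    (EECT-lncRNAs) in tumor cohorts with a mean + 3 SD outlier rule on
    log2 expression, and runs the downstream analyses: evolutionary
    conservation scoring of exons and promoters, guilt-by-association
    functional annotation through Spearman co-expression with
    hypergeometric pathway enrichment over an expanded annotation
    database, strand-aware enrichment of testis-specific regulatory
    elements in flanking windows, mutation mutual-exclusivity screening,
    and covariate-adjusted association models. Ships a synthetic-cohort
    generator with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
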