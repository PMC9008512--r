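Package: ceRNAflow
Title: Simulation and Discovery of lncRNA-miRNA-mRNA ceRNA Networks in
    Staged Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for competing endogenous RNA (ceRNA) network discovery
    from staged bulk transcriptome experiments, modelled on the analysis of
    female strobilus bud differentiation in Ginkgo biloba. Implements the
    lncRNA identification cascade (GffCompare class codes, length filter,
    open-reading-frame coding-potential rule), FPKM/RPM normalisation, a
    negative-binomial Wald test for adjacent-stage differential expression
    with Benjamini-Hochberg correction, Mfuzz-style fuzzy c-means clustering
    of temporal profiles, plant-style miRNA target-site scanning, cis
    (10 kb window) and trans (pairing energy) lncRNA target assignment,
    correlation-filtered lncRNA-miRNA-mRNA triplet integration, and
    hypergeometric term enrichment. Ships a synthetic-data generator with
    planted ground truth (temporal prototypes, ceRNA triplets, cis pairs)
    so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    mclust
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
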