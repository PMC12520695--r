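Package: screenrank
Title: Pooled CRISPR Screen Enrichment Ranking and Robust Rank Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pooled CRISPR screens selected through
    severe population bottlenecks. Implements exact-match sgRNA
    quantification from amplicon reads, an in vivo lung-metastasis
    enrichment ranking (per-sample total-count normalization, low-coverage
    exclusion, per-mouse fold change against an input baseline, cross-mouse
    averaging and best-guide-per-gene ranking), candidate triage against
    interactome protein lists, alpha robust rank aggregation with a
    permutation null and Benjamini-Hochberg FDR for fluorescence-ratio
    sorting screens, and a seeded synthetic-data generator that emulates the
    statistical structure of both screen designs (overdispersed library
    representation, clonal metastatic bottlenecks with driver genes, and
    two-gate reporter-stability sorts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
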