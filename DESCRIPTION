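Package: interactomeScan
Title: Candidate-Interactome Enrichment Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests whether the human genes whose protein products physically
    interact with an environmental factor (a "candidate interactome", e.g. the
    human targets of a viral proteome) are enriched in genome-wide association
    signals. SNP-level association p-values are mapped to genes within a 20 kb
    window, each gene is represented by its most associated (index) SNP,
    gene-level signals are pruned for linkage disequilibrium, and per-interactome
    empirical enrichment p-values are obtained from size-matched random gene
    sets sampled with gene-size (SNP-count) weights, with a second bootstrap
    level of simulated studies for study-wide assessment. Includes evidence-based
    curation of interactomes from interaction tables, region masking for
    MHC-style dual analyses, multi-cutoff sensitivity scans, and a synthetic
    GWAS generator with LD blocks and spiked gene-set signal so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
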