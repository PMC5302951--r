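Package: cdmir
Title: Identification of Cell-Death-Related miRNAs by Target-Set
    Enrichment and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for prioritising microRNAs that
    regulate programmed cell death in a disease context. For each miRNA,
    predicted target genes are tested for over-representation in apoptosis
    and autophagy gene sets with an exact upper-tail hypergeometric test;
    enriched miRNAs are intersected with differentially expressed miRNAs
    from paired tumour/normal expression profiling (two-tailed t-test),
    candidates are split into known and novel against a curated cell-death
    miRNA list, and the predicted set is evaluated against the known list
    by a resampling null with an exact analytic twin. A synthetic-data
    generator with planted ground truth emulates the target network, the
    gene annotation, the paired expression matrices and the known list, so
    the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
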