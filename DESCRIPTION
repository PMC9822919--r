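Package: xtwas
Title: Summary-Statistic Transcriptome-Wide Association Testing with
    Multi-Tissue Exclusivity Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds genetically-predicted gene expression models from
    cis-eQTL summary statistics (within-gene FDR filtering, greedy LD
    clumping against a reference panel, per-variant 2pq*beta^2 variance
    accounting and a gene-level variance-explained filter), computes
    summary-statistic gene-trait association z-scores against GWAS
    summary statistics using reference-panel covariance, pools results
    across tissues under study-wide Bonferroni correction to classify
    tissue-exclusive genes, and tests gene-set over-representation.
    Includes a blocked-LD simulator that generates reference panels,
    multi-tissue eQTL summary statistics and GWAS summary statistics
    with known ground truth, so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'association.R'
    'enrichment.R'
    'methods.R'
    'modelBuilder.R'
    'multiTissue.R'
    'simulate.R'
    'xtwas-package.R'
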