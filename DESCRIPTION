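Package: tomnet
Title: Transcriptional Override Model Analysis for miRNA-Repressor-Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the transcriptional override model (TOM) analysis of
    two-condition mRNA/miRNA expression data. From expression matrices,
    miRNA target-prediction tables and transcription-factor regulon gene
    sets, the pipeline selects differentially expressed genes and
    upregulated miRNAs, classifies predicted miRNA targets as inversely
    correlated, positively correlated or unchanged, selects downregulated
    repressor genes that are themselves miRNA targets, assembles the
    miRNA-repressor-target feed-forward network, and quantifies override of
    miRNA repression by repressor loss via degree-stratified
    Cochran-Armitage trend tests and log-space hypergeometric enrichment.
    A synthetic-data generator plants the full TOM structure with known
    ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
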