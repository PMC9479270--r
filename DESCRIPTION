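Package: reversalnet
Title: Treatment-Reversal Transcript Analysis and lncRNA-mRNA Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for three-group (control / disease / treated)
    expression studies: per-contrast fold-change and Welch-t differential
    expression with intensity and length filters, intersection of transcripts
    whose regulation direction is reversed by treatment, fold-change-ranked
    selection of key lncRNAs, Pearson-correlation bipartite lncRNA-mRNA
    co-expression network construction with analytic p-values, core-mRNA
    sub-network extraction, hypergeometric gene-set over-representation, and
    2^-ddCt relative quantification of qPCR Ct tables. Includes a synthetic
    microarray study generator with planted ground truth for recovery testing,
    and a bundled 33-lncRNA reversal table from a rat collagen-induced
    arthritis study as a worked fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
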