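Package: adiporeg
Title: Stage-Aware Integration of Expression and Binding Evidence During
    Adipocyte Differentiation
Version: 0.1.0
Authors@R:
    person("Morgan", "Carter", email = "m.carter@example.org",
           role = c("aut", "cre"))
Description: Tools for studying transcriptional regulation of autophagy
    genes across the stages of 3T3-L1 adipocyte differentiation. The
    package stages time-course samples (non/early/late), performs
    negative-binomial Wald differential expression on gene counts and
    differential binding on ChIP-seq reads-in-peaks counts, computes
    Fisher-z differential co-expression with permutation-based empirical
    p- and q-values, runs exact hypergeometric gene-set
    over-representation tests, annotates peaks to nearest genes with
    promoter-window classification, aggregates promoter occupancy, and
    integrates all evidence streams into classified direct/indirect
    regulatory links with knockdown-consistency checks. A synthetic-data
    generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    DESeq2,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
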