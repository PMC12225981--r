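Package: tekaryo
Title: Transposable-Element Expression Analysis Across Sex-Chromosome Karyotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transposable-element (TE) expression at the subfamily
    level from per-copy count tables, normalizes TE counts with gene-anchored
    median-of-ratios size factors, and tests how TE expression depends on
    sex-chromosome karyotype (46,XX; 46,XY; 47,XXY; 47,XYY). Provides the
    per-sample global TE-expression proportion with rank-based group
    comparisons, negative-binomial differential expression with Wald and
    likelihood-ratio tests, exact-binomial classification of Y-chromosome
    enrichment of TE subfamilies, permutation and binomial tests for TE-copy
    enrichment near and within differentially expressed genes, and a
    karyotype-structured count simulator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
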