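Package: coralheat
Title: Comparative Thermal-Stress Transcriptomics for Coral Holobionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative analysis of coral holobiont
    transcriptome responses to acute heat stress. From per-species gene-level
    count matrices and annotation tables it performs representative-isoform
    selection, host/symbiont transcript binning from best BLAST hits,
    domain-based stress-response-gene (SRG) cataloguing, negative-binomial
    exact-test differential expression at strict fold-change thresholds,
    multivariate ordination with permutational ANOVA and a transcriptome
    plasticity distance statistic, and classification of frontloaded versus
    stress-responsive SRGs. A synthetic-data generator plants known
    differential-expression, binning, and frontloading structure so every
    stage of the pipeline is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
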