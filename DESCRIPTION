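Package: wlmmqtl
Title: Weighted Linear Mixed Model Mapping of cis eQTL/sQTL SNPs and
    SNP-Induced Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of multi-dataset RNA-seq expression profiles of
    genotyped cell lines. Fits weighted linear mixed models (random
    cell-line effect, per-group inverse-variance weights) and their
    heteroscedastic and ordinary fixed-effects reductions to test additive
    SNP genotype effects on gene expression (eQTL) and genotype-by-exon
    interaction effects on rescaled exon expression indexes (sQTL).
    Includes composite-LD SNP pruning, permutation-based FDR thresholds,
    cis and trans association scans, gene-anchored genomic-region
    classification with density indexes, assembly of cis-to-trans
    regulatory relationships into four network paradigms with hub modules
    and target-distribution summaries, and a synthetic-data generator that
    reproduces the grouped, replicated, heteroscedastic study design for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
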