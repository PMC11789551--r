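Package: nestmeth
Title: Sex-Specific Differential DNA Methylation for Cross-Fostered Nestling Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide CpG methylation in maternal-effect
    field experiments with partial cross-fostering. Fits per-CpG binomial
    generalized linear mixed models (logit link, Laplace approximation, crossed
    brood-of-origin and brood-of-rearing random intercepts), tests
    treatment-by-sex interactions by likelihood-ratio test with
    Benjamini-Hochberg false discovery rate control, excludes overdispersed
    sites via the highest density interval of the Pearson dispersion statistic,
    classifies sex-specific differentially methylated sites into
    female-specific, male-specific, antagonistic and other categories, and
    annotates sites to prioritized genomic regions (TSS, promoter, gene body,
    up/downstream) from GFF3 gene models. Includes maximum-likelihood Gaussian
    mixed models for nestling phenotypes (growth, begging, handling-stress
    breath-rate slopes) and a synthetic-data generator that emulates the
    cross-fostered experimental design so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
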