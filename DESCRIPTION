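Package: gxsreml
Title: Sex-Stratified Bivariate GREML for Gene-by-Sex Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of sex-specific SNP heritabilities and cross-sex
    genetic correlations from genome-wide genotype data using restricted
    maximum likelihood (REML) on a bivariate linear mixed model in which
    male and female phenotypes are treated as two traits sharing a genomic
    relationship matrix. Provides constrained model fits (genetic
    correlation fixed at one; equal heritabilities via a residual-ratio
    reparametrization) with one-degree-of-freedom likelihood ratio tests,
    genotype and phenotype quality-control filters, genomic-relationship-
    matrix construction with GCTA-format input/output, PLINK bed/bim/fam
    input/output, GBLUP back-solving of per-SNP effects for sex-specific
    and sex-agnostic genomic prediction, and a synthetic-cohort generator
    with known gene-by-sex architecture for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
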