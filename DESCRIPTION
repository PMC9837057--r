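Package: sexgwas
Title: Sex-Aware Analysis of GWAS and eQTL Summary Statistics in Drug
    Metabolism Gene Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting sex-differentiated genetic effects from
    sex-stratified genome-wide association study (GWAS) and expression
    quantitative trait locus (eQTL) summary statistics, with a focus on
    drug metabolism enzyme and transporter (DMET) gene regions.  Provides
    summary-statistics input/output with allele harmonization, z-score
    tests for sex differences in heritability and per-variant effects,
    calling of variants with sex-differentiated effects (SDEs) under
    false-discovery-rate control, a two-step multiple-testing correction
    and classifier for sex-differentiated and sex-specific eQTLs,
    approximate-Bayes-factor colocalization with sex-stratified
    interpretation, sex-combined and sex-stratified MR-Egger Mendelian
    randomization, a permutation test for enrichment of associations in
    gene regions, and a seedable synthetic-data generator (linkage
    disequilibrium aware genotype panels, sex-stratified phenotypes,
    MR and colocalization scenarios) so every stage is testable without
    access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
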