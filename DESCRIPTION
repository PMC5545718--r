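Package: subtypeHerit
Title: SNP Heritability and Genetic Correlation Contrasts for Disease
    Subtypes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Variance-component analysis of genetic heterogeneity between
    subtypes of a complex disease. Implements genetic relationship
    matrices and average-information REML for SNP-based heritability on
    the observed and liability scales, bivariate REML genetic
    correlations between disjoint case cohorts sharing split controls, a
    permutation contrast comparing subtype-pair against mixed-cohort
    genetic correlations, logistic association scans with fixed-effects
    meta-analysis and Cochran's Q, genomic inflation, direction-of-effect
    sign tests, and polygenic risk scoring with Nagelkerke delta-R2
    subtype contrasts. A liability-threshold cohort simulator with two
    correlated disease subtypes, a quality-control pipeline with the
    standard GWAS thresholds, and PLINK bed/bim/fam plus GCTA-style GRM
    text input/output make every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
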