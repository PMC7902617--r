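Package: phstrat
Title: Polygenic Hazard Score Survival Analysis and Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes polygenic hazard scores (PHS) from effect-allele
    dosages and per-SNP weights, adapts a score across genotyping platforms
    by linkage-disequilibrium proxy substitution and weight re-estimation,
    fits sample-weighted Cox proportional hazards models of age at prostate
    cancer diagnosis or death with a case-control incidence correction,
    reports percentile-anchored hazard-ratio contrasts with stratified
    bootstrap confidence intervals, assigns genetic-ancestry labels from
    admixture proportions, and quantifies sensitivity of hazard ratios to
    the assumed population incidence. Includes a synthetic-cohort generator
    emulating ancestry-divergent allele frequencies, Hardy-Weinberg
    genotypes with LD-correlated proxy pairs, a PHS-driven proportional
    hazards age-at-onset process with right censoring, case-control
    enrichment, aggressive and fatal sub-endpoints, and family history
    correlated with genetic risk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
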