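Package: prsinteract
Title: Polygenic Risk Scoring and Gene-by-Environment Interaction Testing
    for Cannabis Use and Psychotic Experiences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline relating self-reported cannabis use to
    self-reported psychotic experiences under modulation by schizophrenia
    polygenic risk. Implements polygenic risk score (PRS) construction from
    GWAS summary statistics (variant quality control, allele and strand
    harmonization, p-value thresholding selected by AUC, linkage
    disequilibrium pruning, mean-imputed scoring), covariate-adjusted
    logistic association with ordinal exposure codings and coefficient
    difference tests, and gene-by-environment interaction likelihood-ratio
    tests with covariate-interaction adjustment and Benjamini-Hochberg
    false discovery rate control. A liability-threshold synthetic-cohort
    generator provides genotypes, an independent-cohort GWAS, and phenotyped
    individuals with the statistical structure the analysis assumes, so the
    full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
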