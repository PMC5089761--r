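Package: msrisk
Title: Composite Genetic and Environmental Risk Scoring for Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an additive log10-odds multiple sclerosis (MS) risk score
    combining published environmental odds ratios (sex, birth month,
    infectious mononucleosis, anti-EBNA-1 IgG quintile, deseasonalised serum
    25-hydroxyvitamin D quintile, smoking) with genetic contributions from
    HLA-DRB1*1501 zygosity and a 57-SNP susceptibility panel. Provides
    weight-ledger construction from odds ratios with confidence-interval
    based zeroing, phenotype encoding (cotinine-adjudicated smoking status,
    cosinor deseasonalisation, reference-quintile assignment), VCF and dosage
    genotype readers, four score variants, cohort analytics (rank-based AUC
    with DeLong confidence intervals, one-way ANOVA with Bonferroni post-hoc
    testing, septile risk stratification), a pooled-variance two-proportion
    sample-size calculator, and a family-structured cohort simulator with
    Mendelian sibling genotype sharing for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
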