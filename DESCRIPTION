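Package: eppgrm
Title: Extra-Pair Paternity Inference from Genomic Relatedness in
    Cavity-Nesting Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers extra-pair paternity in socially monogamous birds from
    SNP genotypes and field nest records. Builds a genomic relatedness
    matrix with the GCTA estimator, compares it against the field-observed
    social pedigree using threshold bands to classify within-pair,
    extra-pair, half-sibling and brood-parasitism relationships, discovers
    sex-linked markers and assigns nestling sex with a cross-validated
    classifier, computes breeding-density and breeding-synchrony metrics
    with species-specific fertile windows, and fits the binomial GLM/GLMM
    battery relating promiscuity to spatiotemporal covariates. Ships a
    synthetic-data generator emulating two-plot tit populations (Mendelian
    transmission, distance-decay extra-pair sire choice, ZW sex linkage,
    genotyping error and missingness) so every stage is testable without
    field data.
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
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
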