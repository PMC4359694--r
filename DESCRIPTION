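Package: grsburden
Title: Disease-Burden Genetic Risk Scores in Family-Based Longevity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds disease-specific unweighted genetic risk scores (GRS) from
    GWAS-catalog-style SNP association tables, compares risk-allele rates
    between members of families selected for exceptional longevity and
    married-in spousal controls using family-aware Poisson rate models
    (mixed-effects, GEE with sandwich variance, and kinship-corrected linear
    mixed models), runs a configurable sensitivity battery (APOE-region SNP
    removal, stricter LD pruning, published GRS subsets, external control
    substitution), and estimates study power by family-structured simulation.
    Includes a synthetic cohort generator emulating a two-generation family
    study design (pedigrees, LD-blocked genotypes with Mendelian transmission,
    and a multiplicative familial-longevity effect on risk-allele rates) so
    the whole pipeline is testable without restricted genotype data.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
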