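Package: braingap
Title: Voxel-Based Brain Age Estimation and Brain-Age-Gap Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates brain age from registered gray-matter probability maps by
    high-dimensional elastic-net regression trained on a reference cohort of
    cognitively normal subjects, transfers the model to a target cohort, applies
    a linear age-bias correction, and computes the brain age gap (BAG). Provides
    the downstream association suite used in brain-age epidemiology: tertile
    stratification, Cox proportional-hazards mortality models with a
    cause-specific competing-risk variant, least-squares-mean contrasts across
    cognitive-status groups, covariate-adjusted phenotype regressions, and a
    proteome-wide association scan with Bonferroni and false-discovery-rate
    control. A synthetic-cohort simulator generates template-space gray-matter
    volumes with a planted atrophy signal, phenotypes, site-censored survival
    outcomes, and an aptamer-scale protein panel for validation and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
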