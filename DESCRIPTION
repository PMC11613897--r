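Package: brcascreen
Title: Evaluation of Population Genetic Screening Strategies for Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for population-level breast
    cancer risk stratification combining rare pathogenic variants in BRCA1,
    BRCA2, PALB2, ATM and CHEK2 with a polygenic risk score (PRS) and
    EHR-derived family history. Provides a synthetic EHR+genotype cohort
    generator calibrated to published hazard ratios and cumulative incidence,
    a rule-based ClinVar/LOFTEE variant-classification cascade, group-wise
    PRS percentile normalization with dosage fallback, Kaplan-Meier and Cox
    proportional-hazards risk read-outs, family-history ascertainment-timing
    analysis, and screening-strategy metrics (PPV, specificity,
    number-needed-to-screen, false negatives).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
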