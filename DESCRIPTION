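Package: sexcheck
Title: Sex-Incongruence Data Quality Assessment for OMOP-Style EHR Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens electronic health record condition-occurrence data for
    prevalent sex-specific conditions and quantifies record plausibility with
    condition-specific and overall incongruence rates (CIR/OIR), including
    Wald confidence intervals and small-cell suppression for public reporting.
    Profiles participants with incongruent records by genomic-sex concordance,
    concurrent and multiple sex-specific conditions, coarse (zip3) geography
    and condition start year, and supports a sensitivity analysis that
    re-admits non-cisgender participants. Ships a seeded synthetic cohort
    generator emulating an OMOP-lite extract (person, condition_occurrence,
    concept, genomic sex, zip3 tables) with a tunable record-misassignment
    error rate, a closed-form expectation of the induced overall incongruence
    rate for parameter-recovery checks, and a config-driven pipeline runner
    that writes reproducible report bundles.
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
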