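Package: gmhi
Title: Gut Microbiome Health Index from Species-Level Metagenomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Gut Microbiome Health Index (GMHI), a log-ratio
    score that compares the collective abundance of health-prevalent
    microbial species against that of health-scarce species in a stool
    metagenome taxonomic profile. Provides the full workflow: reading and
    merging MetaPhlAn-style relative-abundance profiles, sample- and
    feature-level quality filtering, prevalence-based discovery of the two
    species sets under joint fold-change and difference thresholds, grid
    search of the thresholds by balanced accuracy with stratified
    cross-validation, per-sample scoring and sign classification with the
    packaged 50-species signature, companion alpha-diversity and
    effect-size statistics, and a synthetic-cohort generator with planted
    prevalence differentials for validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
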