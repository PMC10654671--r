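Package: methaneguilds
Title: Functional Guild Classification and Community Analysis for Landfill Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-annotation inference for metagenome-assembled genomes (MAGs)
    from landfill and similar engineered methane-cycling ecosystems. Provides
    coverage-based relative abundance profiles, a rule engine that classifies
    methanogen MAGs into substrate guilds (strictly hydrogenotrophic,
    acetoclastic, methylotrophic, broad-substrate) from marker genes and
    stepwise pathway-completion tables, identification of aerobic and anaerobic
    (ANME) methanotrophs with scaffold-level verification for novel families,
    four-category acetogen screening, Bray-Curtis/NMDS community ordination,
    harmonization of legacy taxon names to GTDB families for cross-study
    occurrence analysis, and a seed-controlled synthetic data generator with
    planted ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    vegan,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
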