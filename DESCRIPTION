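Package: alkconcord
Title: Concordance Analysis of ALK Rearrangement Testing by FISH, IHC and NGS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies per-nucleus fluorescence in situ hybridization (FISH)
    signal configurations from ALK break-apart and tri-color ALK/EML4 fusion
    probes into rearrangement pattern classes (inversion, translocation,
    5-prime deletion, interstitial deletion, 3-prime deletion), aggregates
    nuclei to sample-level positivity calls with a sectioning-artifact
    derivation rule and copy-number-gain categories, integrates
    immunohistochemistry and next-generation sequencing evidence into
    diagnostic concordance classes, and provides the exact contingency-table
    inference used to compare pattern distributions between concordant and
    discordant cases (Fisher's exact test for 2xK tables by full enumeration,
    Cramer's V with a noncentral chi-square confidence interval, Laplace
    smoothing). A seeded synthetic-cohort generator emulates per-nucleus
    signal observations for positive/negative x concordant/discordant case
    archetypes so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
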