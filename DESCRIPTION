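Package: lipidelta
Title: Differential Analysis of Targeted Shotgun Lipidomics (MRM) Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested workflow for two-group comparisons of targeted shotgun
    lipidomics (multiple-reaction-monitoring, MRM) measurements. Raw
    counts-per-second are normalized to deuterated per-class internal
    standards, technical duplicates are averaged per animal, and species are
    optionally re-expressed as fractions of their lipid-class total. Species-
    and class-level effects are summarized as fold changes with a dual
    significance/effect-size filter (Student t-test p-value plus a
    mean-SEM effect threshold), Benjamini-Hochberg FDR adjustment,
    direction-of-regulation binomial tests, and acyl chain-length and
    saturation profiles. A synthetic MRM data generator with known ground
    truth (group effects, biological and technical noise, matrix drift on
    standards) makes every stage testable without instrument data. Utilities
    for body-surface-area human-equivalent dose conversion and delta-delta-Ct
    qPCR relative expression are included.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
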