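Package: anclick
Title: Lick Microstructure and Anticipatory Negative Contrast Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing licking behaviour in anticipatory negative
    contrast (ANC) experiments: reading timestamped lick and port-entry event
    logs, segmenting lick trains into clusters by an inter-lick-interval
    criterion, deriving per-phase microstructure metrics (total licks, total
    clusters, licks per cluster, premature port entries), building normalized
    experimental/control contrast tables across paired sessions, and running
    the within-subject statistical battery (two-way repeated-measures ANOVA,
    three-way mixed ANOVA with Greenhouse-Geisser correction, Bonferroni
    post-hoc tests, and emergence-session detection). A generative simulator
    of the two-phase drinking paradigm produces cluster-structured synthetic
    cohorts so every pipeline stage can be exercised and calibrated without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
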