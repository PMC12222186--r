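Package: saltmeta
Title: Cross-Setting Dose-Response Meta-Analysis of Crop Salt-Stress Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dose-response meta-analysis of plant salt-stress
    studies conducted in heterogeneous experimental settings (field, outdoor
    pots, greenhouse, climate chamber). Normalizes salinity measurements to
    electrical conductivity, derives relative (stress/control) response
    ratios and stress integrals, partitions the stress axis into adaptive
    bins with per-setting count constraints, removes outliers with a
    single-pass Hampel (median absolute deviation) filter, and compares
    settings pairwise with a gated test-selection procedure (Shapiro-Wilk
    and Brown-Forsythe gates choosing between a permutation t-test and a
    Mann-Whitney U test). Also provides the companion factorial analysis
    (two-way ANOVA with a residual-normality gate falling back to the
    Scheirer-Ray-Hare rank test) and a seeded synthetic study-corpus
    generator for calibration and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
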