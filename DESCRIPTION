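Package: ringphys
Title: Retrospective Tree-Ring Carbon Isotope Physiology and Biomass
    Increment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs annually resolved physiological parameters of
    conifers from tree rings: carbon isotope discrimination, intercellular
    CO2 concentration and intrinsic water-use efficiency from wood delta-13C
    together with an atmospheric CO2/delta-13C record; whole-tree biomass and
    annual biomass increment from ring widths via published allometric
    models; inter-annual variability (mean sensitivity); adaptive
    power-transform plus cubic-smoothing-spline detrending with a frequency
    cutoff criterion; seasonal growth-climate Spearman correlations; and
    linear mixed-effect contrasts of pollution-defined calendar periods with
    Tukey comparisons and marginal/conditional pseudo-R-squared. Includes a
    synthetic-data generator reproducing the statistical structure of
    mountain Norway spruce chronologies so the whole pipeline can be run and
    validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
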