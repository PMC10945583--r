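Package: triadose
Title: Dose-Response Analysis and Cross-Route Dose Equivalence for
    Voluntary Oral THC Consumption in Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for voluntary oral THC (edible gelatin)
    consumption studies in mice: consumption dosimetry (grams eaten,
    mg/kg dose, piecewise intake rates with a changepoint, non-consumer
    fractions), cannabimimetic triad difference scores (hypolocomotion,
    tail-flick analgesia, hypothermia) with three-parameter Emax
    dose-response fitting and ED50 estimation, acoustic startle
    dose-response summaries with second-order polynomial fits by sex,
    and the cross-route dose-prediction model that inverts fitted
    intraperitoneal dose-response curves at observed oral-consumption
    responses to obtain i.p.-equivalent doses, propagates them through
    the startle polynomial, and validates predictions against measured
    startle. Includes a synthetic cohort generator reproducing the
    statistical structure these analyses assume, from-scratch summary
    statistics (SEM, one- and two-way ANOVA with subject blocking,
    Sidak adjustment, regression F-test), descriptive pharmacokinetic
    summaries, and CSV/YAML/JSON input-output with a reproducible
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
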