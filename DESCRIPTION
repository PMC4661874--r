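Package: comboEff
Title: Dose-Response, Combination-Index and Xenograft Efficacy Analysis
    for Preclinical Drug-Combination Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for preclinical combination-therapy studies
    of the kind run on SRB (sulforhodamine B) viability plates and mouse
    xenografts. Estimates IC50 values per condition from 96-well
    dose-response data (log-linear interpolation or four-parameter
    logistic fit, aggregated over independent experiments), computes the
    mutually non-exclusive Chou-Talalay combination index at a fixed
    effect level -- including triple combinations measured over a
    fixed-dose background agent -- and classifies interactions as
    synergism, additivity or antagonism. For in vivo arms it computes
    caliper tumor volumes, per-group median volumes, tumor growth
    inhibition (TGI) and the hypothetical TGI expected under Bliss
    independence of two single agents, plus body-weight toxicity
    summaries and nonparametric group comparisons. A seeded synthetic
    data generator emulates plate and animal tables with the statistical
    structure the analyses assume, so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
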