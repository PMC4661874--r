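# comboEff

Dose-response, combination-index and xenograft efficacy analysis for
preclinical drug-combination studies.

Preclinical combination programs — e.g. a tyrosine kinase inhibitor
paired with cytostatics and/or vitamin D analogs — generate two data
types: 96-well SRB viability plates and mouse xenograft caliper series.
comboEff turns both into the field's standard efficacy quantities, with a
seeded synthetic-data generator so the whole pipeline is testable without
external data. It is aimed at analysts of in vitro / in vivo combination
experiments who want the arithmetic behind their summary tables to be
reproducible and tested.

## What it computes

**In vitro.** Per-condition IC50s from plate wells (log-linear
interpolation between the doses bracketing 50% inhibition, or a
four-parameter logistic fit), aggregated as mean ± SD over independent
experiments. The mutually non-exclusive Chou–Talalay combination index at
the IC50,

    CI = d_A/D_A + d_B/D_B + (d_A d_B)/(D_A D_B),

where `D` are single-agent concentrations reaching the effect and `d` the
concentrations doing so in the combination — including triple
combinations where both are measured over a fixed-dose background agent.
Calls: CI < 0.8 synergism, 0.8–1.2 additive, > 1.2 antagonism; an
undefined CI (single-agent IC50 out of tested range) is reported as
"countless", not an error. A Bliss-independence surface
(1 − (1 − fa_A)(1 − fa_B)) backs interaction calls where CIs are
undefined.

**In vivo.** Caliper tumor volume V = (a² × b)/2 (a the shorter
diameter), per-group/day medians, tumor growth inhibition
TGI = 100 × (1 − VT/VC), and the hypothetical TGI a combination would
show if its two single agents acted independently,
HTGI = 100 × (1 − (VT_A/VC)(VT_B/VC)) — the in vivo synergy benchmark —
plus body-weight toxicity summaries and Mann–Whitney / Kruskal–Wallis
group comparisons.

## Worked example

The package ships the published per-group median tumor volumes of an
A549 lung-cancer xenograft study (imatinib "GV" with the vitamin D
analog PRI-2191, subcutaneous vs oral):

```r
library(comboEff)
med <- a549MedianVolumes()
v <- function(g, d) med$median_volume_mm3[med$group == g & med$day == d]

tgi(v("PRI-2191 s.c.", 14), v("vehicle (control)", 14))
#> [1] 36
tgi(v("GV", 21), v("vehicle (control)", 21))
#> [1] -6
htgi(v("PRI-2191 s.c.", 14), v("GV", 14), v("vehicle (control)", 14))
#> [1] 45
```

Day 14: the analog alone inhibits tumor growth by 36%; imatinib alone is
inactive at Day 21 (−6%, tumors slightly larger than control); under
independence the s.c. combination would be expected to reach 45% — the
observed combination median (76 mm³, TGI 51%) beats it, the signature of
in vivo synergy.

An end-to-end in vitro run on synthetic data:

```r
truths <- list(HillTruth("GV", ic50 = 100))
wells <- simulatePlate(truths,
  PlateDesign("GV", 10^seq(0, 4, 0.25), nExperiments = 4L,
              noiseCv = 0.1, seed = 7))
est <- ic50ByExperiment(wells, "GV", method = "4pl")
ic50(est)
#> [1] 100.3681
```

A thin command-line front end over the same functions lives at
`inst/scripts/comboeff.R` (subcommands `simulate` / `ic50` / `ci` /
`invivo` / `full`, YAML-configured).

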