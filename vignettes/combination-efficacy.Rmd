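---
title: "Quantifying drug-combination efficacy in vitro and in vivo with comboEff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug-combination efficacy in vitro and in vivo with comboEff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboEff)
```

## The problem

Preclinical combination studies of targeted agents (here, the tyrosine
kinase inhibitor imatinib) with cytostatics and vitamin D analogs ask two
questions at two scales. In vitro: does adding a second (or a fixed-dose
third) compound shift a cell line's dose-response enough to call the
interaction synergistic rather than merely additive? In vivo: does the
combination slow xenograft tumor growth more than the two monotherapies
would if they acted independently? comboEff implements both analyses as a
tested pipeline — from plate-well viabilities (SRB-style percent-of-control
readings) to IC50 tables with combination indices, and from per-mouse
caliper measurements to tumor-growth-inhibition tables — plus a seeded
synthetic-data generator that emulates both data types so every stage can
be validated against known ground truth.

## Dose-response model and IC50 estimation

A well's viability is its reading divided by the mean vehicle-control
reading of the same experiment (`normalizeViability()`); the fraction
affected is fa = 1 − mean viability per dose (`buildCurve()`). Two IC50
estimators are exposed, and every report names the one used:

* **Log-linear interpolation** (`ic50Interpolate()`, the default, matching
  common SRB practice): the first pair of ascending doses bracketing
  fa = 0.5 is interpolated linearly in log10(dose). Curves that never
  reach 0.5 get status `above_range` (no value — the analog whose IC50
  lies above the tested range is the canonical case); curves already past
  0.5 at the lowest dose get `below_range` with the bottom dose flagged.
  Negative fa values (wells above control) are retained for fitting but
  clipped to 0 for the bracketing search, keeping the crossing search
  well defined without discarding information.
* **Four-parameter logistic** (`ic50FourPL()`):
  fa(d) = bottom + (top − bottom) / (1 + (IC50/d)^slope), fitted by
  Levenberg–Marquardt least squares with bounds keeping IC50 and slope
  positive (bottom ∈ [−0.5, 1], top ∈ [0, 1.5], slope ∈ [0.05, 20]).
  Non-convergence (a flat curve, say) falls back to interpolation with an
  explicit flag rather than failing.

Per-experiment estimates are combined by `aggregateExperiments()` as mean
± sample (n−1) SD over experiments with status `ok`, the convention used
when assays are run in triplicate and repeated 3–5 times; out-of-range
experiments are excluded and counted, never silently averaged in.

Units are never converted implicitly. Each dose carries its native unit
(ng/mL for cytostatics, nM for vitamin D analogs) and mixing units within
a condition is an error — a deliberate guard against the easiest silent
mistake in multi-agent plates.

## Combination index and interaction calls

At a fixed effect level F (the IC50, F = 0.5), the mutually non-exclusive
Chou–Talalay combination index is

CI = d_A/D_A + d_B/D_B + (d_A·d_B)/(D_A·D_B),

with D the single-agent concentrations reaching F and d the
concentrations doing so in the combination. The cross-product term is
what makes the form appropriate for mechanistically independent drugs;
the package's property tests verify symmetry, per-agent scale invariance
(units cancel), and that the non-exclusive CI exceeds the two-term
exclusive form by exactly the cross term. Calls use the study cutoffs:
CI < 0.8 synergism, CI > 1.2 antagonism, 0.8–1.2 additive, with the
boundaries belonging to the additive band. An undefined CI — a
single-agent IC50 outside the tested range leaves a denominator
unavailable — is a first-class result rendered "countless", never an
exception.

For triple combinations, the fixed-dose background agent defines the
measurement context: D_A is the titrated agent's IC50 alone *within the
same background column*, and D_B the partner's single-agent IC50 under
that background. This within-column reading is the only one that keeps F
fixed when the background itself shifts the titrated agent's IC50. The
combination's d_B is the partner's fixed plate dose, since the design
varies only one agent. `ciGrid()` applies these semantics over a whole
screen table; a background agent whose own IC50 is out of range never
blocks the pairwise CI.

Where single-agent IC50s needed for a CI are unavailable, a
Bliss-independence comparison stands in: `blissExpectedInhibition()`
computes the expected combined fraction affected 1 − (1 − fa_A)(1 − fa_B),
and `plotBasedCall()` calls synergism/additivity/antagonism from the mean
signed excess of the observed combination curve over that surface. The
call tolerance defaults to 0.05 fraction-affected — there is no numeric
rule in the plot-reading tradition this mimics, so the default is sized
to absorb triplicate noise at CV 0.10 and is configurable.

## In vivo efficacy

Tumor volume from two perpendicular caliper diameters is
V = (a² × b)/2 with a the shorter diameter (`tumorVolume()`; argument
order is irrelevant). Groups are summarized by per-day medians over the
mice present that day, so animals lost to follow-up drop out without
imputation. Tumor growth inhibition is

TGI = 100 × (1 − VT/VC),

VT and VC the treated and control medians on the same day (no
interpolation across days). The sign is chosen so inhibition reads
positive; the literal "(VT/VC) × 100 − 100%" form yields the opposite
sign, and reports carry a footnote saying so. The **hypothetical TGI** of
a combination is the Bliss-independence expectation on volume ratios from
its two monotherapy groups:

HTGI = 100 × (1 − (VT_A/VC) × (VT_B/VC)),

algebraically tgi(V_A·V_B/VC, VC). A combination whose observed TGI
exceeds its HTGI is doing better than independent action — the in vivo
synergy benchmark. All outputs label it "hypothetical TGI (independence
expectation)". Both percentages are rounded to the nearest integer, half
away from zero, *only* at reporting; internal values keep full precision.

Body-weight toxicity is the percent change of group mean weight from the
treatment-start baseline over mice weighed on both days; group contrasts
use the standard two-tailed Mann–Whitney/Wilcoxon or Kruskal–Wallis tests
(delegated to `stats`), read at p < 0.05.

```{r invivo-example}
med <- a549MedianVolumes()  # packaged published median-volume table
v <- function(g, d) med$median_volume_mm3[med$group == g & med$day == d]
tgi(v("PRI-2191 s.c.", 14), v("vehicle (control)", 14))
htgi(v("PRI-2191 s.c.", 14), v("GV", 14), v("vehicle (control)", 14))
```

## The synthetic-data generator

`simulatePlate()` draws percent-of-control well readings whose noise-free
expectation is the Bliss-combined survival of all agents present, each
following a Hill curve (inhibition = Emax·d^h/(d^h + IC50^h)); readings
get multiplicative lognormal noise with configurable CV (default 0.10,
a typical plate-reader figure) and are clipped to [0, 1.5] to mimic
raw-absorbance artifacts. Defaults mirror the emulated assay: triplicate
wells, three experiments, dose grids in the agents' native units. The
generator emits already-normalizable percent-of-control readings rather
than raw optical densities, since blank/control plate layout is an
assay-specific detail the analyses never see.

`simulateTumorStudy()` grows each mouse's volume as
v0·exp(r·(1 − e)·t) — r the control growth rate, e the fractional
growth-rate reduction, t days since treatment start — with lognormal
noise, and emits caliper diameters reconstructing the noisy volume
exactly. Since (a² × b)/2 is underdetermined by V alone, a = b = (2V)^(1/3)
unless an eccentricity b/a is requested. Body weight follows its own
exponential trend. Typical study shapes (7–9 mice per group,
measurements from Day 7 to ~Day 31) are the intended regime.

All randomness flows from one explicit integer seed through a
save/restore wrapper, so identical configurations give byte-identical
tables and simulation never perturbs the caller's RNG stream.

What the generator does *not* emulate — plate edge effects, spatial
drift, pipetting serial correlation, inter-mouse growth-rate
heterogeneity beyond lognormal volume noise, early deaths — bounds what
passing tests show: they validate the estimators against the assumed
noise model, not against every artifact of real plates and colonies.

## Numerical and design choices

* **Acceptance-scale simulations.** The stochastic IC50-recovery check
  runs 200 simulated studies (3 replicates × 4 experiments, CV 0.10) on a
  17-dose grid, 4 doses per decade over 4 decades bracketing the true
  IC50. The span matters: a Cramér–Rao analysis of the free 4PL under
  this noise shows 2-decade grids leave the IC50 information-limited
  (per-experiment SD ≈ 18%) because top, bottom and slope are then barely
  identified, while the 4-decade bracketing design is well conditioned.
  Plates meant for 4PL analysis should observe both asymptotes.
* **Interpolation vs 4PL.** On noise-free Hill curves sampled at ≥ 4
  points per decade with the IC50 bracketed, the two estimators agree
  within 2%; interpolation is the default because the plate-level
  software tradition it matches makes no parametric assumption.
* **Ties and rounding.** TGI/HTGI report half-away-from-zero integers;
  exact .5 ties cannot arise from exact division, so the rule only
  matters under floating-point coincidence.
* **Degenerate inputs.** Constant-fa curves exercise the 4PL fallback;
  empty (group, day) cells return NA ("missing-data signal") rather than
  erroring; malformed CSV rows are dropped, counted and reported with
  their row numbers.
* **CSV dialect.** UTF-8, comma-separated, dot decimal, mandatory
  header. Animal columns carry units in their names (`diam_a_mm`,
  `weight_g`); plate doses carry a per-row `dose_unit` column instead,
  because one plate file may legitimately mix agents with different
  native units.

## Limitations

The combination-index machinery is fixed-effect-level by design: no
median-effect regression (Dm, m), no isobolograms, no CI at effect levels
other than the configured F. In vivo analysis is summary-statistic based
(medians, rank tests); no mixed-effects growth modeling or survival
analysis. Published IC50 magnitudes for specific cell lines are not
recomputable from summary tables alone, so the in vitro stage is
validated by parameter recovery on synthetic data rather than against
printed means.
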