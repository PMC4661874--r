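#' @import methods
NULL

## ---------------------------------------------------------------------------
## Ground-truth and design classes for the synthetic-data generator
## ---------------------------------------------------------------------------

#' Hill-curve ground truth for one agent
#'
#' Parameters of the sigmoid inhibition curve used to simulate plate data:
#' inhibition(d) = maxInhibition * d^h / (d^h + ic50^h). With
#' `maxInhibition = 1` the curve passes through exactly 0.5 at the IC50.
#' Doses and the IC50 are in the agent's native unit (`unit`), e.g. ng/mL
#' for cytostatics or nM for vitamin D analogs; the package never converts
#' units implicitly.
#'
#' @slot agentId agent label.
#' @slot ic50 half-maximal inhibitory concentration (> 0), native unit.
#' @slot hillSlope Hill coefficient (> 0), dimensionless.
#' @slot maxInhibition plateau inhibition fraction in (0, 1].
#' @slot unit concentration unit string (e.g. "ng/mL", "nM").
#' @export
setClass("HillTruth",
  representation(agentId = "character", ic50 = "numeric",
                 hillSlope = "numeric", maxInhibition = "numeric",
                 unit = "character"),
  prototype(hillSlope = 1, maxInhibition = 1, unit = "ng/mL"))

setValidity("HillTruth", function(object) {
  msg <- character()
  if (length(object@agentId) != 1L || !nzchar(object@agentId))
    msg <- c(msg, "agentId must be a non-empty string")
  if (length(object@ic50) != 1L || is.na(object@ic50) || object@ic50 <= 0)
    msg <- c(msg, "ic50 must be a single positive number")
  if (length(object@hillSlope) != 1L || object@hillSlope <= 0)
    msg <- c(msg, "hillSlope must be positive")
  if (length(object@maxInhibition) != 1L ||
      object@maxInhibition <= 0 || object@maxInhibition > 1)
    msg <- c(msg, "maxInhibition must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Plate design for simulated dose-response experiments
#'
#' Describes one titration: an agent varied over an increasing dose grid,
#' optionally over a fixed-dose background (e.g. PRI-2191 at 10 or 100 nM),
#' with triplicate wells per dose and several independent experiments, as
#' in a standard 96-well SRB layout.
#'
#' @slot variedAgent label of the titrated agent.
#' @slot variedDoses strictly increasing positive dose grid (native unit).
#' @slot doseUnit unit of the varied doses.
#' @slot background data.frame (`agent`, `dose`, `unit`) of fixed-dose
#'   agents; zero rows for single-agent plates.
#' @slot replicatesPerDose wells per dose per experiment (>= 1; default 3).
#' @slot nExperiments number of independent experiments (default 3).
#' @slot noiseCv coefficient of variation of the multiplicative reading
#'   noise (default 0.10).
#' @slot seed integer seed driving all randomness of the simulation.
#' @export
setClass("PlateDesign",
  representation(variedAgent = "character", variedDoses = "numeric",
                 doseUnit = "character", background = "data.frame",
                 replicatesPerDose = "integer", nExperiments = "integer",
                 noiseCv = "numeric", seed = "integer"),
  prototype(doseUnit = "ng/mL",
            background = data.frame(agent = character(), dose = numeric(),
                                    unit = character()),
            replicatesPerDose = 3L, nExperiments = 3L, noiseCv = 0.10,
            seed = 1L))

setValidity("PlateDesign", function(object) {
  msg <- character()
  d <- object@variedDoses
  if (length(d) < 1L || any(d <= 0) || any(diff(d) <= 0))
    msg <- c(msg, "variedDoses must be strictly increasing and positive")
  if (object@replicatesPerDose < 1L)
    msg <- c(msg, "replicatesPerDose must be >= 1")
  if (object@nExperiments < 1L)
    msg <- c(msg, "nExperiments must be >= 1")
  if (object@noiseCv < 0)
    msg <- c(msg, "noiseCv must be >= 0")
  if (nrow(object@background) &&
      !all(c("agent", "dose", "unit") %in% names(object@background)))
    msg <- c(msg, "background needs columns agent, dose, unit")
  if (length(msg)) msg else TRUE
})

#' Exponential tumor-growth ground truth for one treatment group
#'
#' Group-level parameters for the xenograft simulator. Tumor volume of
#' each mouse follows v0 * exp(growthRate * (1 - treatmentEffect) * t)
#' with multiplicative lognormal noise, t counted in days from treatment
#' start; body weight follows baselineWeight * exp(weightTrend * t).
#'
#' @slot groupLabel treatment-group label.
#' @slot v0 median tumor volume at treatment start, mm^3 (> 0).
#' @slot growthRate control exponential growth rate per day (> 0).
#' @slot treatmentEffect fractional growth-rate reduction in [0, 1).
#' @slot weightTrend per-day fractional body-weight change (negative for
#'   toxicity-driven loss).
#' @slot baselineWeight body weight at treatment start, g.
#' @slot nMice group size (>= 1).
#' @slot noiseCv coefficient of variation of volume / weight noise.
#' @export
setClass("GrowthTruth",
  representation(groupLabel = "character", v0 = "numeric",
                 growthRate = "numeric", treatmentEffect = "numeric",
                 weightTrend = "numeric", baselineWeight = "numeric",
                 nMice = "integer", noiseCv = "numeric"),
  prototype(treatmentEffect = 0, weightTrend = 0, baselineWeight = 22,
            nMice = 8L, noiseCv = 0.10))

setValidity("GrowthTruth", function(object) {
  msg <- character()
  if (object@v0 <= 0) msg <- c(msg, "v0 must be > 0")
  if (object@growthRate <= 0) msg <- c(msg, "growthRate must be > 0")
  if (object@treatmentEffect < 0 || object@treatmentEffect >= 1)
    msg <- c(msg, "treatmentEffect must be in [0, 1)")
  if (object@nMice < 1L) msg <- c(msg, "nMice must be >= 1")
  if (object@baselineWeight <= 0) msg <- c(msg, "baselineWeight must be > 0")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Analysis result classes
## ---------------------------------------------------------------------------

#' Dose-effect curve for one condition
#'
#' Mean fraction affected (fa = 1 - mean viability) at each dose of a
#' varied agent, for a fixed background. Doses are stored ascending.
#' Small negative fa values (wells reading above control) are retained and
#' flagged; values below -0.5 violate validity.
#'
#' @slot variedAgent titrated agent label.
#' @slot background data.frame (`agent`, `dose`, `unit`); zero rows if none.
#' @slot doses strictly increasing doses (native unit).
#' @slot fa mean fraction affected per dose, in [-0.5, 1].
#' @slot nReplicates number of wells averaged per dose.
#' @slot doseUnit unit of `doses`.
#' @slot flags character vector of data-quality flags.
#' @export
setClass("DoseEffectCurve",
  representation(variedAgent = "character", background = "data.frame",
                 doses = "numeric", fa = "numeric", nReplicates = "integer",
                 doseUnit = "character", flags = "character"),
  prototype(background = data.frame(agent = character(), dose = numeric(),
                                    unit = character()),
            flags = character()))

setValidity("DoseEffectCurve", function(object) {
  msg <- character()
  if (length(object@doses) < 2L)
    msg <- c(msg, "a curve needs at least 2 doses")
  if (any(object@doses <= 0) || any(diff(object@doses) <= 0))
    msg <- c(msg, "doses must be strictly increasing and positive")
  if (length(object@fa) != length(object@doses))
    msg <- c(msg, "fa and doses must have equal length")
  if (any(object@fa < -0.5 | object@fa > 1, na.rm = TRUE))
    msg <- c(msg, "fa values must lie in [-0.5, 1]")
  if (length(object@nReplicates) != length(object@doses))
    msg <- c(msg, "nReplicates must match doses")
  if (length(msg)) msg else TRUE
})

#' IC50 estimate for one condition
#'
#' Result of `ic50Interpolate()`, `ic50FourPL()` or
#' `aggregateExperiments()`. `status` records whether 50% inhibition was
#' reached inside the tested dose range: `"ok"`, `"above_range"` (curve
#' never reaches 0.5; IC50 above the top dose) or `"below_range"` (already
#' past 0.5 at the lowest dose). Aggregates over experiments carry the
#' per-experiment values plus mean and sample (n-1) SD.
#'
#' @slot variedAgent,background,doseUnit condition identity, as in
#'   [DoseEffectCurve-class].
#' @slot value point estimate (NA when out of range).
#' @slot method "interpolation" or "four_parameter_logistic".
#' @slot status "ok", "above_range" or "below_range".
#' @slot perExperiment per-experiment IC50 values (aggregates only).
#' @slot mean,sd mean and sample SD over ok-status experiments (NA when
#'   not applicable; sd needs >= 2 experiments).
#' @slot nExcluded number of out-of-range experiments excluded.
#' @slot flags data-quality / fallback flags.
#' @export
setClass("IC50Estimate",
  representation(variedAgent = "character", background = "data.frame",
                 doseUnit = "character", value = "numeric",
                 method = "character", status = "character",
                 perExperiment = "numeric", mean = "numeric", sd = "numeric",
                 nExcluded = "integer", flags = "character"),
  prototype(background = data.frame(agent = character(), dose = numeric(),
                                    unit = character()),
            value = NA_real_, perExperiment = numeric(), mean = NA_real_,
            sd = NA_real_, nExcluded = 0L, flags = character()))

setValidity("IC50Estimate", function(object) {
  msg <- character()
  if (!object@status %in% c("ok", "above_range", "below_range"))
    msg <- c(msg, "status must be ok, above_range or below_range")
  if (!object@method %in% c("interpolation", "four_parameter_logistic"))
    msg <- c(msg, "method must be interpolation or four_parameter_logistic")
  if (!is.na(object@sd) && object@sd < 0)
    msg <- c(msg, "sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Chou-Talalay combination-index result
#'
#' The mutually non-exclusive combination index at a fixed effect level F
#' together with its interaction call. An undefined CI (a single-agent
#' IC50 outside the tested range makes the denominator unavailable) is a
#' first-class value: `ci` is NA and `category` is "undefined", never an
#' error.
#'
#' @slot ci combination index (> 0) or NA when undefined.
#' @slot category "synergism", "additive", "antagonism" or "undefined".
#' @slot effectLevel the fraction affected F at which CI was evaluated.
#' @slot inputs named list with elements DA, DB, dA, dB (concentrations:
#'   each agent alone vs in the combination at effect F) and optional
#'   `background` data.frame.
#' @export
setClass("CIResult",
  representation(ci = "numeric", category = "character",
                 effectLevel = "numeric", inputs = "list"),
  prototype(ci = NA_real_, category = "undefined", effectLevel = 0.5,
            inputs = list()))

setValidity("CIResult", function(object) {
  msg <- character()
  if (!object@category %in%
      c("synergism", "additive", "antagonism", "undefined"))
    msg <- c(msg, "invalid category")
  if (!is.na(object@ci) && object@ci <= 0)
    msg <- c(msg, "a defined ci must be > 0")
  if (is.na(object@ci) && object@category != "undefined")
    msg <- c(msg, "NA ci requires category 'undefined'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

#' @describeIn HillTruth-class constructor.
#' @param agentId,ic50,hillSlope,maxInhibition,unit see slots.
#' @export
HillTruth <- function(agentId, ic50, hillSlope = 1, maxInhibition = 1,
                      unit = "ng/mL") {
  new("HillTruth", agentId = agentId, ic50 = as.numeric(ic50),
      hillSlope = as.numeric(hillSlope),
      maxInhibition = as.numeric(maxInhibition), unit = unit)
}

#' @describeIn PlateDesign-class constructor.
#' @param variedAgent,variedDoses,doseUnit,background,replicatesPerDose,nExperiments,noiseCv,seed see slots.
#' @export
PlateDesign <- function(variedAgent, variedDoses, doseUnit = "ng/mL",
                        background = NULL, replicatesPerDose = 3L,
                        nExperiments = 3L, noiseCv = 0.10, seed = 1L) {
  if (is.null(background))
    background <- data.frame(agent = character(), dose = numeric(),
                             unit = character(), stringsAsFactors = FALSE)
  new("PlateDesign", variedAgent = variedAgent,
      variedDoses = as.numeric(variedDoses), doseUnit = doseUnit,
      background = background,
      replicatesPerDose = as.integer(replicatesPerDose),
      nExperiments = as.integer(nExperiments),
      noiseCv = as.numeric(noiseCv), seed = as.integer(seed))
}

#' @describeIn GrowthTruth-class constructor.
#' @param groupLabel,v0,growthRate,treatmentEffect,weightTrend,baselineWeight,nMice,noiseCv see slots.
#' @export
GrowthTruth <- function(groupLabel, v0, growthRate, treatmentEffect = 0,
                        weightTrend = 0, baselineWeight = 22, nMice = 8L,
                        noiseCv = 0.10) {
  new("GrowthTruth", groupLabel = groupLabel, v0 = as.numeric(v0),
      growthRate = as.numeric(growthRate),
      treatmentEffect = as.numeric(treatmentEffect),
      weightTrend = as.numeric(weightTrend),
      baselineWeight = as.numeric(baselineWeight),
      nMice = as.integer(nMice), noiseCv = as.numeric(noiseCv))
}

## ---------------------------------------------------------------------------
## show() methods
## ---------------------------------------------------------------------------

setMethod("show", "HillTruth", function(object) {
  cat(sprintf("HillTruth '%s': IC50 = %g %s, slope = %g, Emax = %g\n",
              object@agentId, object@ic50, object@unit, object@hillSlope,
              object@maxInhibition))
})

setMethod("show", "PlateDesign", function(object) {
  bg <- formatBackground(object@background)
  cat(sprintf(
    "PlateDesign: %s over %d doses [%g..%g %s]%s\n  %d replicate(s) x %d experiment(s), noise CV %.2f, seed %d\n",
    object@variedAgent, length(object@variedDoses),
    min(object@variedDoses), max(object@variedDoses), object@doseUnit,
    if (nzchar(bg)) paste0(" + background ", bg) else "",
    object@replicatesPerDose, object@nExperiments, object@noiseCv,
    object@seed))
})

setMethod("show", "GrowthTruth", function(object) {
  cat(sprintf(
    "GrowthTruth '%s': v0 = %g mm^3, rate = %g/day, effect = %g, %d mice\n",
    object@groupLabel, object@v0, object@growthRate,
    object@treatmentEffect, object@nMice))
})

setMethod("show", "DoseEffectCurve", function(object) {
  bg <- formatBackground(object@background)
  cat(sprintf("DoseEffectCurve: %s%s (%d doses, %s)\n", object@variedAgent,
              if (nzchar(bg)) paste0(" + ", bg) else "",
              length(object@doses), object@doseUnit))
  print(data.frame(dose = object@doses, fa = round(object@fa, 4),
                   n = object@nReplicates))
  if (length(object@flags))
    cat("flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "IC50Estimate", function(object) {
  bg <- formatBackground(object@background)
  cat(sprintf("IC50Estimate: %s%s [%s]\n", object@variedAgent,
              if (nzchar(bg)) paste0(" + ", bg) else "", object@method))
  if (length(object@perExperiment)) {
    cat(sprintf("  mean %s sd over %d experiment(s): %g %s %s %s\n",
                "±", length(object@perExperiment), object@mean,
                object@doseUnit, "±",
                ifelse(is.na(object@sd), "NA", format(object@sd))))
    if (object@nExcluded > 0L)
      cat(sprintf("  %d out-of-range experiment(s) excluded\n",
                  object@nExcluded))
  } else {
    cat(sprintf("  value: %s %s (status: %s)\n",
                ifelse(is.na(object@value), "NA", format(object@value)),
                object@doseUnit, object@status))
  }
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CIResult", function(object) {
  cat(sprintf("CIResult: CI = %s -> %s (at F = %g)\n",
              ifelse(is.na(object@ci), "countless", format(object@ci)),
              object@category, object@effectLevel))
})
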