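#' Mutually non-exclusive Chou-Talalay combination index
#'
#' For two compounds reaching a common effect level F (here the IC50,
#' F = 0.5), the mutually non-exclusive combination index is
#'
#'   CI = dA/DA + dB/DB + (dA * dB) / (DA * DB)
#'
#' where DA and DB are the concentrations of each agent *alone* giving F,
#' and dA, dB the concentrations of the agents *in the combination*
#' giving the same F. The third (cross-product) term distinguishes the
#' non-exclusive form, appropriate for drugs with independent mechanisms,
#' from the two-term exclusive form. When either single-agent
#' concentration is unavailable (its IC50 fell outside the tested range)
#' the CI is undefined — a first-class result, not an error.
#'
#' All four quantities may have been measured over a fixed-dose third
#' agent (e.g. a vitamin D analog background); pass it as `background`
#' for bookkeeping. dA must share units with DA, and dB with DB; the two
#' pairs may use different units since only ratios enter.
#'
#' @param DA,DB concentrations of A and B alone giving effect F (NA when
#'   out of range).
#' @param dA,dB concentrations of A and B in the combination giving F.
#' @param effectLevel the fraction affected F (default 0.5, the IC50).
#' @param background optional data.frame (`agent`, `dose`, `unit`)
#'   recording the fixed-dose context.
#' @param lower,upper classification thresholds passed to [classifyCI()].
#' @return a [CIResult-class].
#' @examples
#' # half of each single-agent dose: CI = 0.5 + 0.5 + 0.25 = 1.25
#' ciValue(combinationIndex(DA = 10, DB = 4, dA = 5, dB = 2))
#' @export
combinationIndex <- function(DA, DB, dA, dB, effectLevel = 0.5,
                             background = NULL, lower = 0.8, upper = 1.2) {
  inputs <- list(DA = DA, DB = DB, dA = dA, dB = dB)
  if (!is.null(background)) inputs$background <- background
  defined <- !vapply(list(DA, DB, dA, dB),
                     function(x) is.null(x) || length(x) != 1L || is.na(x),
                     logical(1))
  if (!all(defined))
    return(new("CIResult", ci = NA_real_, category = "undefined",
               effectLevel = effectLevel, inputs = inputs))
  if (any(c(DA, DB, dA, dB) <= 0))
    stop("all defined concentrations must be positive", call. = FALSE)
  ci <- dA / DA + dB / DB + (dA * dB) / (DA * DB)
  new("CIResult", ci = ci,
      category = classifyCI(ci, lower = lower, upper = upper),
      effectLevel = effectLevel, inputs = inputs)
}

#' Classify a combination index
#'
#' Interaction call at the study's cutoffs: CI < 0.8 synergism,
#' CI > 1.2 antagonism, CI in [0.8, 1.2] additive (boundaries belong to
#' additive). NA passes through as `"undefined"`. The three defined
#' categories partition (0, Inf) exhaustively and without overlap.
#'
#' @param ci numeric combination-index vector (NA allowed).
#' @param lower,upper additive-band boundaries (default 0.8 and 1.2).
#' @return character vector of categories.
#' @examples
#' classifyCI(c(0.629, 0.995, 1.266, NA))
#' @export
classifyCI <- function(ci, lower = 0.8, upper = 1.2) {
  stopifnot(lower < upper)
  if (any(ci <= 0, na.rm = TRUE))
    stop("a combination index must be positive", call. = FALSE)
  ifelse(is.na(ci), "undefined",
         ifelse(ci < lower, "synergism",
                ifelse(ci > upper, "antagonism", "additive")))
}

#' Combination-index grid over cytostatics, doses and background levels
#'
#' Computes one CI per table cell of a fixed-dose combination screen in
#' which one agent (e.g. imatinib) is titrated against each cytostatic
#' held at a fixed plate dose, within each background level (e.g.
#' 0 / 10 / 100 nM of a vitamin D analog). Per row the inputs are:
#' DA = the titrated agent's IC50 alone *under the same background*,
#' dA = its IC50 in the combination, dB = the cytostatic's fixed plate
#' dose, DB = the cytostatic's single-agent IC50 under that background.
#' A missing DA or DB (out-of-range IC50) yields an undefined cell, not
#' a failure; in particular a background agent whose own IC50 is out of
#' range never blocks the pairwise CI.
#'
#' @param grid data.frame with one row per (cytostatic, cytostatic dose,
#'   background level) and columns: `cytostatic`, `cytostatic_dose`,
#'   `cytostatic_unit`, `background` (string, "" for none),
#'   `varied_ic50_alone` (DA), `varied_ic50_combo` (dA), `varied_unit`,
#'   `cytostatic_ic50_alone` (DB, same unit as `cytostatic_dose`).
#' @param effectLevel,lower,upper passed to [combinationIndex()].
#' @return the input data.frame with `ci` and `category` columns added;
#'   the list of [CIResult-class] objects is attached as attribute
#'   `"results"`.
#' @export
ciGrid <- function(grid, effectLevel = 0.5, lower = 0.8, upper = 1.2) {
  need <- c("cytostatic", "cytostatic_dose", "cytostatic_unit",
            "background", "varied_ic50_alone", "varied_ic50_combo",
            "varied_unit", "cytostatic_ic50_alone")
  missing <- setdiff(need, names(grid))
  if (length(missing))
    stop("ciGrid input lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  results <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid[i, ]
    combinationIndex(DA = r$varied_ic50_alone,
                     DB = r$cytostatic_ic50_alone,
                     dA = r$varied_ic50_combo,
                     dB = r$cytostatic_dose,
                     effectLevel = effectLevel,
                     background = parseBackground(r$background),
                     lower = lower, upper = upper)
  })
  out <- grid
  out$ci <- vapply(results, ciValue, numeric(1))
  out$category <- vapply(results, ciCategory, character(1))
  attr(out, "results") <- results
  out
}

#' Bliss-independence expected inhibition
#'
#' Null-model combined effect of two agents acting independently:
#' expected fraction affected 1 - (1 - faA)(1 - faB), i.e. survivals
#' multiply. Used both as the reference surface for plot-based
#' interaction calls and as the kernel of the in vivo hypothetical TGI.
#'
#' @param faA,faB fractions affected in [0, 1] (vectorized).
#' @return expected combined fraction affected.
#' @examples
#' blissExpectedInhibition(0.3, 0.3)  # 0.51
#' @export
blissExpectedInhibition <- function(faA, faB) {
  if (any(faA < 0 | faA > 1 | faB < 0 | faB > 1, na.rm = TRUE))
    stop("fractions affected must lie in [0, 1]", call. = FALSE)
  1 - (1 - faA) * (1 - faB)
}

#' Plot-based interaction call against the Bliss surface
#'
#' Numeric stand-in for judging proliferation-inhibition plots by eye:
#' compares the observed combination curve against the Bliss expectation
#' built from the single-agent curve and the fixed partner's fraction
#' affected, on a matched dose grid. The mean signed excess of observed
#' over expected fa decides the call: above `tolerance` synergism, below
#' `-tolerance` antagonism, otherwise additive.
#'
#' @param curveCombo [DoseEffectCurve-class] of the varied agent measured
#'   with the fixed-dose partner present.
#' @param curveA [DoseEffectCurve-class] of the varied agent alone, on
#'   the same dose grid.
#' @param faB fraction affected of the fixed-dose partner alone.
#' @param tolerance call threshold on mean fa excess (default 0.05,
#'   sized to absorb triplicate noise at CV 0.10).
#' @return one of `"synergism"`, `"additive"`, `"antagonism"`, with the
#'   mean excess attached as attribute `"excess"`.
#' @export
plotBasedCall <- function(curveCombo, curveA, faB, tolerance = 0.05) {
  stopifnot(is(curveCombo, "DoseEffectCurve"), is(curveA, "DoseEffectCurve"))
  if (length(doses(curveCombo)) != length(doses(curveA)) ||
      any(doses(curveCombo) != doses(curveA)))
    stop("combination and single-agent curves must share a dose grid",
         call. = FALSE)
  expected <- blissExpectedInhibition(pmin(pmax(fractionAffected(curveA),
                                                0), 1), faB)
  excess <- mean(fractionAffected(curveCombo) - expected)
  call <- if (excess > tolerance) "synergism"
          else if (excess < -tolerance) "antagonism" else "additive"
  attr(call, "excess") <- excess
  call
}
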