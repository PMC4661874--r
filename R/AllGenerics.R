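#' Accessors for comboEff result objects
#'
#' Small accessor generics so downstream code never reaches into slots:
#' `doses()` and `fractionAffected()` for [DoseEffectCurve-class],
#' `ic50()` for [IC50Estimate-class] (the point estimate, or the
#' cross-experiment mean for aggregates), `ciValue()` and `ciCategory()`
#' for [CIResult-class], and `conditionLabel()` for a printable
#' "agent + background" condition string.
#'
#' @param object a comboEff S4 object.
#' @return the corresponding slot value (see Details above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("doses", function(object) standardGeneric("doses"))

#' @rdname accessors
#' @export
setGeneric("fractionAffected",
           function(object) standardGeneric("fractionAffected"))

#' @rdname accessors
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))

#' @rdname accessors
#' @export
setGeneric("ic50Status", function(object) standardGeneric("ic50Status"))

#' @rdname accessors
#' @export
setGeneric("ciValue", function(object) standardGeneric("ciValue"))

#' @rdname accessors
#' @export
setGeneric("ciCategory", function(object) standardGeneric("ciCategory"))

#' @rdname accessors
#' @export
setGeneric("conditionLabel",
           function(object) standardGeneric("conditionLabel"))

#' @rdname accessors
#' @export
setMethod("doses", "DoseEffectCurve", function(object) object@doses)

#' @rdname accessors
#' @export
setMethod("fractionAffected", "DoseEffectCurve",
          function(object) object@fa)

#' @rdname accessors
#' @export
setMethod("ic50", "IC50Estimate", function(object) {
  if (length(object@perExperiment)) object@mean else object@value
})

#' @rdname accessors
#' @export
setMethod("ic50Status", "IC50Estimate", function(object) object@status)

#' @rdname accessors
#' @export
setMethod("ciValue", "CIResult", function(object) object@ci)

#' @rdname accessors
#' @export
setMethod("ciCategory", "CIResult", function(object) object@category)

.conditionLabel <- function(agent, background) {
  bg <- formatBackground(background)
  if (nzchar(bg)) paste0(agent, " + ", bg) else agent
}

#' @rdname accessors
#' @export
setMethod("conditionLabel", "DoseEffectCurve", function(object)
  .conditionLabel(object@variedAgent, object@background))

#' @rdname accessors
#' @export
setMethod("conditionLabel", "IC50Estimate", function(object)
  .conditionLabel(object@variedAgent, object@background))
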