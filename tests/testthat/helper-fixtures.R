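# Shared fixture builders: everything is generated in code, no data files.

makeCurve <- function(doses, fa, agent = "GV", background = "",
                      unit = "ng/mL") {
  new("DoseEffectCurve", variedAgent = agent,
      background = parseBackground(background),
      doses = doses, fa = fa,
      nReplicates = rep(3L, length(doses)), doseUnit = unit)
}

# noise-free Hill curve on a log-spaced grid
hillCurve <- function(ic50, slope = 1, doses = 10^seq(0, 4, by = 0.5),
                      top = 1, agent = "X") {
  fa <- top * doses^slope / (doses^slope + ic50^slope)
  makeCurve(doses, fa, agent = agent)
}

okEstimate <- function(value, agent = "GV", unit = "ng/mL") {
  new("IC50Estimate", variedAgent = agent, doseUnit = unit,
      value = value, method = "interpolation", status = "ok")
}

rangeEstimate <- function(status = "above_range", agent = "GV",
                          unit = "ng/mL") {
  new("IC50Estimate", variedAgent = agent, doseUnit = unit,
      value = NA_real_, method = "interpolation", status = status)
}

# small deterministic animal table: two groups, volumes chosen directly
animalTable <- function() {
  # diameters chosen so volumes are easy: a = b = (2V)^(1/3)
  mk <- function(group, day, vols, weights = NULL) {
    a <- (2 * vols)^(1 / 3)
    data.frame(mouse_id = sprintf("%s_%d", group, seq_along(vols)),
               group = group, day = day, diam_a_mm = a, diam_b_mm = a,
               weight_g = if (is.null(weights)) NA_real_ else weights,
               stringsAsFactors = FALSE)
  }
  rbind(mk("control", 7, c(90, 100, 110), c(20, 20, 20)),
        mk("control", 14, c(140, 154, 170), c(20, 21, 19)),
        mk("treated", 7, c(95, 100, 105), c(20, 20, 20)),
        mk("treated", 14, c(90, 98, 120), c(17, 17, 17)))
}
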