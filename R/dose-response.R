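#' Normalize raw plate readings to fraction-of-control viability
#'
#' Divides each raw well reading by the mean vehicle-control reading of
#' the same experiment (solvent controls with no inhibitory effect define
#' 100% proliferation). Readings already expressed as percent of control
#' pass through unchanged when the control mean is 1.
#'
#' @param rawWells data.frame with columns `experiment_id`, `varied_agent`,
#'   `dose`, `dose_unit`, `background`, `replicate` and `reading` (raw
#'   absorbance or equivalent).
#' @param controlWells data.frame with columns `experiment_id` and
#'   `reading`; at least one control per experiment present in `rawWells`.
#' @return the well records with a `viability` column replacing `reading`.
#' @examples
#' raw <- data.frame(experiment_id = "E1", varied_agent = "GV", dose = 10,
#'                   dose_unit = "ng/mL", background = "", replicate = 1,
#'                   reading = 0.8)
#' ctrl <- data.frame(experiment_id = "E1", reading = c(0.9, 1.1))
#' normalizeViability(raw, ctrl)$viability  # 0.8
#' @export
normalizeViability <- function(rawWells, controlWells) {
  stopifnot(is.data.frame(rawWells), is.data.frame(controlWells),
            "reading" %in% names(rawWells),
            all(c("experiment_id", "reading") %in% names(controlWells)))
  ctrlMeans <- tapply(controlWells$reading, controlWells$experiment_id, mean)
  exps <- unique(rawWells$experiment_id)
  noCtrl <- setdiff(exps, names(ctrlMeans))
  if (length(noCtrl))
    stop("no control wells for experiment(s): ",
         paste(noCtrl, collapse = ", "), call. = FALSE)
  bad <- names(ctrlMeans)[ctrlMeans <= 0]
  if (length(bad))
    stop("non-positive control mean in experiment(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- rawWells
  out$viability <- rawWells$reading /
    as.numeric(ctrlMeans[as.character(rawWells$experiment_id)])
  out$reading <- NULL
  out
}

.matchCondition <- function(wells, variedAgent, background) {
  bgStr <- if (is.data.frame(background)) formatBackground(background)
           else as.character(background)
  wells[wells$varied_agent == variedAgent &
          wells$background == bgStr, , drop = FALSE]
}

#' Build a dose-effect curve for one condition
#'
#' Averages well viabilities per dose for a (varied agent, background)
#' condition and converts to fraction affected, fa = 1 - mean viability.
#' Doses come out sorted ascending with per-dose replicate counts.
#'
#' @param wells data.frame of well records (see [simulatePlate()] /
#'   [readPlateCsv()] for the columns).
#' @param variedAgent titrated agent label to select.
#' @param background background selection: a background string as stored
#'   in the `background` column, or a data.frame (`agent`, `dose`,
#'   `unit`); default none.
#' @return a [DoseEffectCurve-class]. Doses with mean fa below 0 are
#'   flagged `"negative_fa"` (wells reading above control).
#' @export
buildCurve <- function(wells, variedAgent, background = "") {
  sel <- .matchCondition(wells, variedAgent, background)
  if (nrow(sel) == 0L)
    stop("no wells for condition '", variedAgent, "' / '",
         if (is.data.frame(background)) formatBackground(background)
         else background, "'", call. = FALSE)
  ds <- sort(unique(sel$dose))
  if (length(ds) < 2L)
    stop("need >= 2 distinct doses to build a curve (got ", length(ds),
         ")", call. = FALSE)
  fa <- vapply(ds, function(d) 1 - mean(sel$viability[sel$dose == d]),
               numeric(1))
  n <- vapply(ds, function(d) sum(sel$dose == d), integer(1))
  unit <- unique(sel$dose_unit)
  if (length(unit) != 1L)
    stop("mixed dose units within one condition: ",
         paste(unit, collapse = ", "), call. = FALSE)
  flags <- character()
  if (any(fa < 0)) flags <- "negative_fa"
  bgdf <- if (is.data.frame(background)) background
          else parseBackground(background)
  new("DoseEffectCurve", variedAgent = variedAgent, background = bgdf,
      doses = ds, fa = fa, nReplicates = n, doseUnit = unit, flags = flags)
}

#' IC50 by log-linear interpolation
#'
#' The default IC50 estimator, matching common SRB-assay practice: scan
#' doses ascending for the first pair bracketing fa = 0.5 and interpolate
#' linearly in log10(dose):
#' log10(IC50) = log10(d_lo) + (0.5 - fa_lo) * (log10(d_hi) -
#' log10(d_lo)) / (fa_hi - fa_lo). Negative fa values are clipped to 0
#' for the bracketing search only. If the curve never reaches 0.5 the
#' status is `"above_range"` with no value; if it is already past 0.5 at
#' the lowest dose the status is `"below_range"` with the minimum dose as
#' a flagged value. Multiple crossings use the first and are flagged.
#'
#' @param curve a [DoseEffectCurve-class].
#' @return an [IC50Estimate-class] with `method = "interpolation"`.
#' @examples
#' cv <- new("DoseEffectCurve", variedAgent = "GV",
#'           doses = c(10, 100), fa = c(0.4, 0.6),
#'           nReplicates = c(3L, 3L), doseUnit = "ng/mL")
#' ic50(ic50Interpolate(cv))  # 10^1.5 = 31.62
#' @export
ic50Interpolate <- function(curve) {
  stopifnot(is(curve, "DoseEffectCurve"))
  d <- curve@doses
  fa <- pmax(curve@fa, 0)  # clip for bracketing only
  flags <- curve@flags

  est <- function(value, status, extra = character())
    new("IC50Estimate", variedAgent = curve@variedAgent,
        background = curve@background, doseUnit = curve@doseUnit,
        value = value, method = "interpolation", status = status,
        flags = c(flags, extra))

  if (fa[1] > 0.5)
    return(est(d[1], "below_range", "ic50_below_tested_range"))

  exact <- which(fa == 0.5)
  crossings <- which(fa[-length(fa)] < 0.5 & fa[-1] >= 0.5)
  if (length(exact) && (!length(crossings) || exact[1] <= crossings[1]))
    return(est(d[exact[1]], "ok",
               if (length(crossings) > 1L) "multiple_crossings"))
  if (!length(crossings))
    return(est(NA_real_, "above_range", "ic50_above_tested_range"))

  i <- crossings[1]
  lg <- log10(d[i]) + (0.5 - fa[i]) * (log10(d[i + 1]) - log10(d[i])) /
    (fa[i + 1] - fa[i])
  est(10^lg, "ok", if (length(crossings) > 1L) "multiple_crossings")
}

#' IC50 by four-parameter logistic fit
#'
#' Least-squares fit of the 4PL model
#' fa(d) = bottom + (top - bottom) / (1 + (ic50 / d)^slope)
#' by Levenberg-Marquardt, with bounds keeping ic50 and slope positive.
#' Non-convergence (e.g. a flat curve) falls back to
#' [ic50Interpolate()] with a `"fit_failed_fallback_interpolation"` flag.
#' A fitted ic50 outside the tested dose range is reported with status
#' `"above_range"` / `"below_range"` and no value, matching the
#' interpolation contract.
#'
#' @param curve a [DoseEffectCurve-class] with >= 4 distinct doses.
#' @return an [IC50Estimate-class] with
#'   `method = "four_parameter_logistic"` (unless the fallback fired).
#'   Fit diagnostics (residual standard error, fitted slope and
#'   asymptotes) are attached as attribute `"fit"`.
#' @export
ic50FourPL <- function(curve) {
  stopifnot(is(curve, "DoseEffectCurve"))
  if (length(curve@doses) < 4L)
    stop("4PL fit needs >= 4 distinct doses", call. = FALSE)
  df <- data.frame(d = curve@doses, fa = curve@fa)

  startIc50 <- {
    ip <- suppressWarnings(ic50Interpolate(curve))
    if (ip@status == "ok") ip@value else exp(mean(log(range(df$d))))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fa ~ bottom + (top - bottom) / (1 + (ic50 / d)^slope),
      data = df,
      start = list(bottom = max(min(df$fa), 0), top = min(max(df$fa), 1),
                   ic50 = startIc50, slope = 1),
      lower = c(bottom = -0.5, top = 0, ic50 = min(df$d) / 1e3, slope = 0.05),
      upper = c(bottom = 1, top = 1.5, ic50 = max(df$d) * 1e3, slope = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    out <- ic50Interpolate(curve)
    out@flags <- c(out@flags, "fit_failed_fallback_interpolation")
    validObject(out)
    return(out)
  }

  cf <- coef(fit)
  value <- unname(cf["ic50"])
  status <- if (value > max(df$d)) "above_range"
            else if (value < min(df$d)) "below_range" else "ok"
  out <- new("IC50Estimate", variedAgent = curve@variedAgent,
             background = curve@background, doseUnit = curve@doseUnit,
             value = if (status == "ok") value else NA_real_,
             method = "four_parameter_logistic", status = status,
             flags = c(curve@flags,
                       if (status != "ok")
                         paste0("fitted_ic50_", status)))
  attr(out, "fit") <- list(coef = cf, sigma = summary(fit)$sigma)
  out
}

#' Estimate an IC50 by the selected method
#'
#' Thin dispatcher over [ic50Interpolate()] and [ic50FourPL()] so
#' pipelines carry the method as configuration.
#'
#' @param curve a [DoseEffectCurve-class].
#' @param method `"interpolation"` (default) or `"4pl"`.
#' @return an [IC50Estimate-class].
#' @export
estimateIC50 <- function(curve, method = c("interpolation", "4pl")) {
  method <- match.arg(method)
  if (method == "interpolation") ic50Interpolate(curve) else ic50FourPL(curve)
}

#' Aggregate per-experiment IC50s into a mean +/- SD estimate
#'
#' Combines IC50 estimates from independent experiments of the same
#' condition the way combination studies report them: mean and sample
#' (n-1) SD over experiments with status `"ok"`, with out-of-range
#' experiments excluded and counted. With a single usable experiment the
#' mean equals that value and the SD is NA. If no experiment is usable
#' the most frequent out-of-range status is propagated.
#'
#' @param estimates list of [IC50Estimate-class] sharing a condition.
#' @return an [IC50Estimate-class] with `perExperiment`, `mean`, `sd`
#'   and `nExcluded` populated.
#' @examples
#' cvs <- lapply(c(20, 22, 24), function(v)
#'   new("IC50Estimate", variedAgent = "GV", doseUnit = "ng/mL",
#'       value = v, method = "interpolation", status = "ok"))
#' aggregateExperiments(cvs)  # mean 22, sd 2
#' @export
aggregateExperiments <- function(estimates) {
  if (is(estimates, "IC50Estimate")) estimates <- list(estimates)
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, is, logical(1), "IC50Estimate")))
  agents <- unique(vapply(estimates, function(e) e@variedAgent, character(1)))
  bgs <- unique(vapply(estimates,
                       function(e) formatBackground(e@background),
                       character(1)))
  units <- unique(vapply(estimates, function(e) e@doseUnit, character(1)))
  if (length(agents) != 1L || length(bgs) != 1L)
    stop("estimates do not share a condition", call. = FALSE)
  if (length(units) != 1L)
    stop("estimates do not share a dose unit", call. = FALSE)
  methods <- unique(vapply(estimates, function(e) e@method, character(1)))

  status <- vapply(estimates, function(e) e@status, character(1))
  ok <- status == "ok"
  vals <- vapply(estimates[ok], function(e) e@value, numeric(1))
  flags <- unique(unlist(lapply(estimates, function(e) e@flags)))

  if (!any(ok)) {
    agg <- names(sort(table(status), decreasing = TRUE))[1]
    return(new("IC50Estimate", variedAgent = agents, doseUnit = units,
               background = estimates[[1]]@background,
               method = methods[1], status = agg,
               perExperiment = numeric(), mean = NA_real_, sd = NA_real_,
               nExcluded = length(estimates), flags = flags))
  }
  new("IC50Estimate", variedAgent = agents, doseUnit = units,
      background = estimates[[1]]@background, method = methods[1],
      status = "ok", value = mean(vals), perExperiment = vals,
      mean = mean(vals),
      sd = if (length(vals) >= 2L) sd(vals) else NA_real_,
      nExcluded = sum(!ok), flags = flags)
}

#' Per-experiment IC50 pipeline for one condition
#'
#' Convenience wrapper: split wells by experiment, build the per-experiment
#' curve, estimate the IC50 with the chosen method, and aggregate.
#'
#' @inheritParams buildCurve
#' @inheritParams estimateIC50
#' @return an aggregated [IC50Estimate-class].
#' @export
ic50ByExperiment <- function(wells, variedAgent, background = "",
                             method = c("interpolation", "4pl")) {
  method <- match.arg(method)
  sel <- .matchCondition(wells, variedAgent, background)
  if (nrow(sel) == 0L)
    stop("no wells for requested condition", call. = FALSE)
  ests <- lapply(split(sel, sel$experiment_id), function(w)
    estimateIC50(buildCurve(w, variedAgent, background), method))
  aggregateExperiments(ests)
}
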