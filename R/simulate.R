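#' Hill inhibition at a dose
#'
#' Fraction of proliferation inhibited at dose `d` under a
#' [HillTruth-class]: `maxInhibition * d^h / (d^h + ic50^h)`; 0 at d = 0.
#'
#' @param truth a [HillTruth-class].
#' @param d numeric dose vector (>= 0, native unit of the truth).
#' @return inhibition fractions in [0, maxInhibition].
#' @examples
#' hillInhibition(HillTruth("GV", ic50 = 100), 100)  # 0.5 at the IC50
#' @export
hillInhibition <- function(truth, d) {
  stopifnot(is(truth, "HillTruth"), all(d >= 0))
  h <- truth@hillSlope
  truth@maxInhibition * d^h / (d^h + truth@ic50^h)
}

#' Simulate a plate of SRB-style dose-response wells
#'
#' Generates percent-of-control viability readings for a titration of one
#' agent, optionally over fixed-dose background agents, mimicking a
#' 96-well SRB experiment repeated in triplicate over several independent
#' experiments. The noise-free viability at dose d is the
#' Bliss-independent combined survival of all agents present,
#' `prod_i (1 - inhibition_i)`; readings are then perturbed by
#' multiplicative lognormal noise with coefficient of variation
#' `design@noiseCv` and clipped to [0, 1.5] to mimic raw-absorbance
#' artifacts. Identical `design@seed` gives identical output.
#'
#' @param truths list of [HillTruth-class], one per agent appearing in the
#'   design (varied or background).
#' @param design a [PlateDesign-class].
#' @return data.frame of well records with columns `experiment_id`,
#'   `varied_agent`, `dose`, `dose_unit`, `background`, `replicate`,
#'   `viability` (one row per experiment x dose x replicate).
#' @examples
#' tr <- list(HillTruth("GV", ic50 = 100))
#' wells <- simulatePlate(tr, PlateDesign("GV", c(10, 100, 1000, 10000),
#'                                        noiseCv = 0, seed = 7))
#' subset(wells, dose == 100)$viability  # exactly 0.5 at the IC50
#' @export
simulatePlate <- function(truths, design) {
  stopifnot(is(design, "PlateDesign"))
  if (is(truths, "HillTruth")) truths <- list(truths)
  ids <- vapply(truths, function(t) t@agentId, character(1))
  names(truths) <- ids
  needed <- c(design@variedAgent,
              if (nrow(design@background)) design@background$agent)
  missing <- setdiff(needed, ids)
  if (length(missing))
    stop("no ground truth for agent(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  bgSurvival <- 1
  if (nrow(design@background)) {
    for (i in seq_len(nrow(design@background))) {
      bt <- truths[[design@background$agent[i]]]
      if (!identical(bt@unit, design@background$unit[i]))
        stop("unit mismatch for background agent '", bt@agentId, "': '",
             design@background$unit[i], "' vs truth '", bt@unit, "'",
             call. = FALSE)
      bgSurvival <- bgSurvival *
        (1 - hillInhibition(bt, design@background$dose[i]))
    }
  }
  vt <- truths[[design@variedAgent]]
  if (!identical(vt@unit, design@doseUnit))
    stop("unit mismatch for varied agent '", vt@agentId, "': design '",
         design@doseUnit, "' vs truth '", vt@unit, "'", call. = FALSE)

  grid <- expand.grid(replicate = seq_len(design@replicatesPerDose),
                      dose = design@variedDoses,
                      experiment_id = sprintf("E%d",
                                              seq_len(design@nExperiments)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expected <- (1 - hillInhibition(vt, grid$dose)) * bgSurvival
  noise <- withSeed(design@seed, rlnormCV(nrow(grid), design@noiseCv))
  viability <- pmin(pmax(expected * noise, 0), 1.5)

  data.frame(experiment_id = grid$experiment_id,
             varied_agent = design@variedAgent,
             dose = grid$dose,
             dose_unit = design@doseUnit,
             background = formatBackground(design@background),
             replicate = grid$replicate,
             viability = viability,
             stringsAsFactors = FALSE)
}

#' Simulate a xenograft tumor-growth study
#'
#' Generates per-mouse caliper and body-weight records for several
#' treatment groups over a measurement schedule, emulating a subcutaneous
#' xenograft experiment with treatment starting at the first listed day.
#' Each mouse's volume follows
#' `v0 * exp(growthRate * (1 - treatmentEffect) * t)` (t = days since
#' treatment start) with multiplicative lognormal noise; the two caliper
#' diameters are emitted so that (a^2 x b)/2 reproduces the noisy volume,
#' with a <= b (a = b = (2V)^(1/3) unless `eccentricity` > 1, in which
#' case b/a = eccentricity). Body weight follows
#' `baselineWeight * exp(weightTrend * t)` with the same noise CV.
#'
#' @param truths list of [GrowthTruth-class], one per group.
#' @param days ascending integer measurement days (days post-inoculation);
#'   the first entry is treatment start.
#' @param seed integer seed for all randomness.
#' @param eccentricity ratio b/a of long to short diameter (>= 1,
#'   default 1: spherical-cap-equivalent equal diameters).
#' @return data.frame of tumor observations with columns `mouse_id`,
#'   `group`, `day`, `diam_a_mm`, `diam_b_mm`, `weight_g`.
#' @examples
#' gr <- list(GrowthTruth("control", v0 = 100, growthRate = 0.15,
#'                        noiseCv = 0))
#' head(simulateTumorStudy(gr, days = c(7, 14, 21), seed = 1))
#' @export
simulateTumorStudy <- function(truths, days, seed = 1L, eccentricity = 1) {
  if (is(truths, "GrowthTruth")) truths <- list(truths)
  if (length(truths) == 0L)
    stop("at least one treatment group is required", call. = FALSE)
  stopifnot(all(vapply(truths, is, logical(1), "GrowthTruth")))
  if (length(days) < 1L || is.unsorted(days, strictly = TRUE))
    stop("'days' must be strictly ascending", call. = FALSE)
  if (eccentricity < 1)
    stop("'eccentricity' must be >= 1", call. = FALSE)

  startDay <- days[1]
  withSeed(seed, {
    rows <- lapply(truths, function(g) {
      t <- rep(days - startDay, each = g@nMice)
      mouse <- sprintf("%s_m%02d", gsub("[^[:alnum:]]+", "_", g@groupLabel),
                       rep(seq_len(g@nMice), times = length(days)))
      vol <- g@v0 * exp(g@growthRate * (1 - g@treatmentEffect) * t) *
        rlnormCV(length(t), g@noiseCv)
      wt <- g@baselineWeight * exp(g@weightTrend * t) *
        rlnormCV(length(t), g@noiseCv)
      a <- (2 * vol / eccentricity)^(1 / 3)
      data.frame(mouse_id = mouse, group = g@groupLabel,
                 day = rep(days, each = g@nMice),
                 diam_a_mm = a, diam_b_mm = eccentricity * a,
                 weight_g = wt, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
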