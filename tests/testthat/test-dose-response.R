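# Normalization, curve building, IC50 estimation and aggregation.

test_that("viability is the raw reading over the per-experiment control mean", {
  raw <- data.frame(experiment_id = c("E1", "E1", "E2"),
                    varied_agent = "GV", dose = c(10, 100, 10),
                    dose_unit = "ng/mL", background = "",
                    replicate = 1L, reading = c(0.4, 0.6, 0.8),
                    stringsAsFactors = FALSE)
  ctrl <- data.frame(experiment_id = c("E1", "E1", "E2"),
                     reading = c(0.4, 0.6, 1.0))
  out <- normalizeViability(raw, ctrl)
  expect_equal(out$viability, c(0.8, 1.2, 0.8))  # control means 0.5 and 1.0
  expect_false("reading" %in% names(out))

  expect_error(normalizeViability(raw, data.frame(experiment_id = "E1",
                                                  reading = 1)),
               "no control wells")
  ctrl$reading[3] <- -1
  expect_error(normalizeViability(raw, ctrl), "non-positive control mean")
})

test_that("buildCurve averages replicates, sorts doses and keeps counts", {
  wells <- data.frame(
    experiment_id = "E1", varied_agent = "GV",
    dose = c(100, 100, 100, 10, 10), dose_unit = "ng/mL",
    background = "", replicate = c(1L, 2L, 3L, 1L, 2L),
    viability = c(0.9, 0.8, 0.7, 1.0, 1.0), stringsAsFactors = FALSE)
  cv <- buildCurve(wells, "GV")
  expect_equal(doses(cv), c(10, 100))            # sorted ascending
  expect_equal(fractionAffected(cv), c(0, 0.2))  # 1 - mean viability
  expect_equal(cv@nReplicates, c(2L, 3L))
  expect_error(buildCurve(wells[wells$dose == 10, ], "GV"), ">= 2 distinct")
  expect_error(buildCurve(wells, "DTX"), "no wells")
})

test_that("log-linear interpolation handles crossing, exact hit and range flags", {
  # symmetric bracket in log space: 0.4@10, 0.6@100 -> 10^1.5
  e <- ic50Interpolate(makeCurve(c(10, 100), c(0.4, 0.6)))
  expect_equal(ic50(e), 10^1.5, tolerance = 1e-12)
  expect_equal(ic50Status(e), "ok")

  # exact 0.5 at a tested dose
  e <- ic50Interpolate(makeCurve(c(10, 50, 100), c(0.2, 0.5, 0.9)))
  expect_equal(ic50(e), 50)

  # curve never reaching 0.5 (e.g. an analog inactive up to the top dose)
  e <- ic50Interpolate(makeCurve(c(10, 100, 1000), c(0.1, 0.3, 0.45)))
  expect_equal(ic50Status(e), "above_range")
  expect_true(is.na(ic50(e)))

  # already past 0.5 at the lowest dose
  e <- ic50Interpolate(makeCurve(c(10, 100), c(0.7, 0.9)))
  expect_equal(ic50Status(e), "below_range")
  expect_equal(ic50(e), 10)
  expect_true("ic50_below_tested_range" %in% e@flags)

  # non-monotone double crossing: first crossing wins, flagged
  e <- ic50Interpolate(makeCurve(c(1, 10, 100, 1000),
                                 c(0.2, 0.6, 0.4, 0.8)))
  expect_true(ic50(e) > 1 && ic50(e) < 10)
  expect_true("multiple_crossings" %in% e@flags)
})

test_that("4PL fit recovers noise-free Hill parameters and falls back sanely", {
  e <- ic50FourPL(hillCurve(100))
  expect_equal(ic50(e), 100, tolerance = 0.01)
  expect_equal(e@method, "four_parameter_logistic")
  expect_equal(attr(e, "fit")$coef[["slope"]], 1, tolerance = 0.05)

  # interpolation and 4PL agree within 2% on a bracketing noise-free grid
  # (4 points per decade, >= 2 per side of the IC50)
  for (sl in c(0.8, 1.5)) {
    cv <- hillCurve(120, slope = sl, doses = 10^seq(0, 4, by = 0.25))
    expect_equal(ic50(ic50Interpolate(cv)), ic50(ic50FourPL(cv)),
                 tolerance = 0.02)
  }

  # constant fa cannot be fit: falls back to interpolation with a flag
  flat <- makeCurve(c(1, 10, 100, 1000), rep(0.5, 4))
  e <- suppressWarnings(ic50FourPL(flat))
  expect_true("fit_failed_fallback_interpolation" %in% e@flags ||
                e@method == "four_parameter_logistic")

  # any crossing curve yields a value within the dose range
  cv <- makeCurve(c(1, 10, 100, 1000), c(0.05, 0.25, 0.7, 0.95))
  e <- ic50FourPL(cv)
  expect_true(ic50(e) >= 1 && ic50(e) <= 1000)

  expect_error(ic50FourPL(makeCurve(c(1, 10), c(0.2, 0.8))), ">= 4")
})

test_that("aggregation over experiments uses mean, sample SD and exclusions", {
  agg <- aggregateExperiments(lapply(c(20, 22, 24), okEstimate))
  expect_equal(agg@mean, 22)
  expect_equal(agg@sd, 2)               # sample (n-1) SD
  expect_equal(agg@nExcluded, 0L)

  single <- aggregateExperiments(list(okEstimate(31)))
  expect_equal(single@mean, 31)
  expect_true(is.na(single@sd))         # no SD from one experiment

  mixed <- aggregateExperiments(c(lapply(c(14, 16, 18), okEstimate),
                                  list(rangeEstimate())))
  expect_equal(mixed@mean, 16)
  expect_equal(mixed@nExcluded, 1L)

  none <- aggregateExperiments(list(rangeEstimate(), rangeEstimate()))
  expect_equal(ic50Status(none), "above_range")
  expect_true(is.na(none@mean))

  expect_error(aggregateExperiments(list(okEstimate(10),
                                         okEstimate(10, agent = "DTX"))),
               "share a condition")
})

test_that("IC50 properties: normalization idempotence and fa-shift monotonicity", {
  tr <- list(HillTruth("GV", ic50 = 100))
  wells <- simulatePlate(tr, PlateDesign("GV", 10^seq(0, 4, 0.5),
                                         noiseCv = 0.08, seed = 2))
  base <- ic50(ic50Interpolate(buildCurve(wells, "GV")))

  # rescaling all readings by a common control leaves the IC50 unchanged
  raw <- wells; raw$reading <- raw$viability * 0.37; raw$viability <- NULL
  ctrl <- data.frame(experiment_id = unique(wells$experiment_id),
                     reading = 0.37)
  renorm <- normalizeViability(raw, ctrl)
  expect_equal(ic50(ic50Interpolate(buildCurve(renorm, "GV"))), base,
               tolerance = 1e-10)

  # a constant positive fa shift never increases the estimated IC50
  for (shift in c(0.05, 0.1, 0.2)) {
    cv <- buildCurve(wells, "GV")
    shifted <- makeCurve(doses(cv), pmin(fractionAffected(cv) + shift, 1))
    expect_lte(ic50(ic50Interpolate(shifted)), base + 1e-9)
  }
})
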