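# Chou-Talalay combination index, classification, CI grids and the
# Bliss-based plot call.

test_that("combinationIndex computes the non-exclusive three-term form", {
  # hand oracle: 7/20 + 0.001/0.004 + (7*0.001)/(20*0.004)
  r <- combinationIndex(DA = 20, DB = 0.004, dA = 7, dB = 0.001)
  expect_equal(ciValue(r), 0.35 + 0.25 + 0.0875, tolerance = 1e-12)
  expect_equal(ciCategory(r), "synergism")

  # half of each single-agent dose: 0.5 + 0.5 + 0.25
  expect_equal(ciValue(combinationIndex(10, 4, 5, 2)), 1.25)

  # dB -> 0 limit reduces to the single-drug ratio dA/DA -> 1
  expect_equal(ciValue(combinationIndex(10, 5, 10, 1e-12)), 1,
               tolerance = 1e-9)

  # undefined single-agent IC50 (out of tested range) -> undefined CI
  u <- combinationIndex(DA = NA, DB = 4, dA = 5, dB = 2)
  expect_true(is.na(ciValue(u)))
  expect_equal(ciCategory(u), "undefined")

  expect_error(combinationIndex(-1, 4, 5, 2), "positive")
})

test_that("classifyCI partitions (0, Inf) with inclusive additive boundaries", {
  expect_equal(classifyCI(c(0.629, 0.995, 1.266, NA)),
               c("synergism", "additive", "antagonism", "undefined"))
  expect_equal(classifyCI(c(0.8, 1.2)), c("additive", "additive"))
  expect_equal(classifyCI(0.7999999), "synergism")
  expect_equal(classifyCI(1.2000001), "antagonism")
  expect_error(classifyCI(-0.5), "positive")
  expect_error(classifyCI(1, lower = 1.2, upper = 0.8), "lower < upper")

  # exhaustive, non-overlapping partition
  ci <- exp(seq(log(0.01), log(100), length.out = 500))
  cat3 <- classifyCI(ci)
  expect_true(all(cat3 %in% c("synergism", "additive", "antagonism")))
  expect_equal(unname(table(cat3)["synergism"]), sum(ci < 0.8))
  expect_equal(unname(table(cat3)["antagonism"]), sum(ci > 1.2))
})

test_that("ciGrid produces one cell per row and tolerates undefined IC50s", {
  grid <- expand.grid(cytostatic = c("DTX", "CIS"),
                      cytostatic_dose = c(0.001, 0.0001),
                      background = c("", "PRI-2191=10 nM",
                                     "PRI-2191=100 nM"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$cytostatic), ]
  grid$cytostatic_unit <- "ug/mL"
  grid$varied_unit <- "ug/mL"
  grid$varied_ic50_alone <- 20
  grid$varied_ic50_combo <- 10
  grid$cytostatic_ic50_alone <- 0.004

  out <- ciGrid(grid)
  expect_equal(nrow(out), 12L)
  expect_true(all(!is.na(out$ci)))
  # a background agent's own out-of-range IC50 never enters the pairwise CI:
  # only DA, DB, dA, dB do, so CIs at 10/100 nM background stay defined
  expect_true(all(out$category[out$background != ""] != "undefined"))

  # a missing cytostatic single-agent IC50 yields an undefined cell, no error
  grid$cytostatic_ic50_alone[1] <- NA
  out2 <- ciGrid(grid)
  expect_equal(out2$category[1], "undefined")
  expect_true(all(out2$category[-1] != "undefined"))

  # identical agents split half/half are Loewe-additive: ci = 1.25 per cell
  loewe <- grid
  loewe$cytostatic_ic50_alone <- 0.004
  loewe$varied_ic50_combo <- 10            # half of DA = 20
  loewe$cytostatic_dose <- 0.002           # half of DB = 0.004
  expect_equal(unique(ciGrid(loewe)$ci), 1.25)

  expect_error(ciGrid(grid[, -1]), "lacks column")
})

test_that("Bliss expected inhibition has its identity and absorbing elements", {
  expect_equal(blissExpectedInhibition(0, 0.37), 0.37)
  expect_equal(blissExpectedInhibition(1, 0.37), 1)
  expect_equal(blissExpectedInhibition(0.3, 0.3), 0.51)
  expect_equal(blissExpectedInhibition(0.2, 0.7),
               blissExpectedInhibition(0.7, 0.2))  # symmetric
  expect_error(blissExpectedInhibition(1.2, 0.5), "\\[0, 1\\]")
})

test_that("plotBasedCall compares the combo curve to the Bliss surface", {
  dosesX <- c(10, 100, 1000)
  faA <- c(0.2, 0.5, 0.8)
  faB <- 0.3
  expected <- blissExpectedInhibition(faA, faB)
  curveA <- makeCurve(dosesX, faA)

  exact <- makeCurve(dosesX, expected)
  expect_equal(plotBasedCall(exact, curveA, faB), "additive",
               ignore_attr = TRUE)

  up <- makeCurve(dosesX, pmin(expected + 0.10, 1))
  expect_equal(plotBasedCall(up, curveA, faB), "synergism",
               ignore_attr = TRUE)

  down <- makeCurve(dosesX, expected - 0.10)
  expect_equal(plotBasedCall(down, curveA, faB), "antagonism",
               ignore_attr = TRUE)

  mismatch <- makeCurve(c(10, 100, 500), expected)
  expect_error(plotBasedCall(mismatch, curveA, faB), "dose grid")
})

test_that("CI algebraic properties hold over random positive quadruples", {
  set.seed(2024)
  n <- 300
  q <- matrix(10^runif(4 * n, -3, 3), ncol = 4)
  for (i in seq_len(n)) {
    DA <- q[i, 1]; DB <- q[i, 2]; dA <- q[i, 3]; dB <- q[i, 4]
    ci <- ciValue(combinationIndex(DA, DB, dA, dB))
    # symmetry under swapping the (alone, combo) pairs of A and B
    expect_equal(ci, ciValue(combinationIndex(DB, DA, dB, dA)))
    # scale invariance: units cancel within each agent's ratio
    k <- 10^runif(1, -2, 2)
    expect_equal(ci, ciValue(combinationIndex(DA * k, DB, dA * k, dB)))
    # exceeds the exclusive two-term form by exactly the cross term
    expect_equal(ci - (dA / DA + dB / DB), (dA * dB) / (DA * DB),
                 tolerance = 1e-9)
  }
})
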