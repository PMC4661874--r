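# Tumor volumes, medians, TGI / hypothetical TGI, body weight and
# nonparametric group comparisons.

test_that("tumorVolume squares the shorter diameter and ignores order", {
  expect_equal(tumorVolume(10, 10), 500)
  expect_equal(tumorVolume(6, 8), 144)
  expect_equal(tumorVolume(8, 6), 144)
  expect_equal(tumorVolume(c(6, 8), c(8, 6)), c(144, 144))
  expect_error(tumorVolume(0, 5), "positive")
})

test_that("groupMedian takes the per-day sample median over available mice", {
  obs <- animalTable()
  expect_equal(groupMedian(obs, "control", 7), 100)    # odd n
  expect_equal(groupMedian(obs, "control", 14), 154)
  # even n averages the two central values
  two <- obs[obs$group == "control" & obs$day == 7, ][1:2, ]
  expect_equal(groupMedian(two, "control", 7), 95)
  # single mouse is its own median; absent (group, day) is NA, not an error
  expect_equal(groupMedian(obs[1, ], "control", 7), 90)
  expect_true(is.na(groupMedian(obs, "control", 99)))
})

test_that("tgi and htgi reproduce the published-style integers and algebra", {
  expect_equal(tgi(98, 154), 36)
  expect_equal(tgi(486, 460), -6)
  expect_equal(tgi(100, 100), 0)
  expect_equal(tgi(98, 154, round = FALSE), 100 * (1 - 98 / 154))
  expect_error(tgi(100, 0), "positive")

  expect_equal(htgi(98, 134, 154), 45)
  expect_equal(htgi(263, 486, 460), 40)
  # inactive partner (vt = vc) reduces htgi to the active agent's tgi
  expect_equal(htgi(154, 98, 154), tgi(98, 154))
  # symmetry in the two single agents
  expect_equal(htgi(98, 134, 154), htgi(134, 98, 154))
  # identity: htgi(vA, vB, vc) = tgi(vA*vB/vc, vc)
  expect_equal(htgi(98, 134, 154, round = FALSE),
               tgi(98 * 134 / 154, 154, round = FALSE))

  # tgi strictly decreasing in vt at fixed vc
  vt <- seq(10, 500, by = 10)
  expect_true(all(diff(tgi(vt, 154, round = FALSE)) < 0))

  # reporting rounds half away from zero (exercised on the helper, since
  # exact .5 ties cannot arise from exact division by 100ths)
  expect_equal(comboEff:::roundHalfOut(c(0.5, -0.5, 44.5, -5.5)),
               c(1, -1, 45, -6))
  expect_equal(tgi(154 * (1 - 0.445), 154), 45)
})

test_that("bodyWeightChange uses mice present at baseline and target day", {
  obs <- animalTable()
  expect_equal(bodyWeightChange(obs, "control", 7, 7), 0)
  expect_equal(bodyWeightChange(obs, "treated", 14, 7), -15)  # 20 g -> 17 g
  expect_equal(bodyWeightChange(obs, "control", 14, 7), 0)    # mean 20 -> 20
  up <- obs; up$weight_g[up$group == "treated" & up$day == 14] <- 22
  expect_equal(bodyWeightChange(up, "treated", 14, 7), 10)
  none <- obs; none$weight_g[none$day == 7] <- NA
  expect_true(is.na(bodyWeightChange(none, "treated", 14, 7)))
})

test_that("compareGroups delegates to two-tailed rank tests", {
  mk <- function(group, vols)
    data.frame(mouse_id = sprintf("%s_%d", group, seq_along(vols)),
               group = group, day = 14,
               diam_a_mm = (2 * vols)^(1 / 3),
               diam_b_mm = (2 * vols)^(1 / 3), stringsAsFactors = FALSE)
  same <- rbind(mk("a", c(100, 200, 300)), mk("b", c(100, 200, 300)))
  expect_gt(compareGroups(same, "a", "b", 14), 0.99)

  far <- rbind(mk("a", 101:108), mk("b", 501:508))
  expect_lt(compareGroups(far, "a", "b", 14), 0.05)
  expect_lt(compareGroups(far, "a", "b", 14, test = "kruskal"), 0.05)

  # permutation of mouse labels within groups leaves p unchanged
  shuf <- far[sample(nrow(far)), ]
  expect_equal(compareGroups(shuf, "a", "b", 14),
               compareGroups(far, "a", "b", 14))

  expect_true(is.na(compareGroups(far[c(1, 9:16), ], "a", "b", 14)))
})

test_that("summarizeTumorGrowth assembles the efficacy table with HTGI", {
  med <- a549MedianVolumes()
  # rebuild per-mouse data whose medians equal the published table exactly:
  # three mice at v-1, v, v+1 have median v
  obs <- do.call(rbind, lapply(seq_len(nrow(med)), function(i) {
    v <- med$median_volume_mm3[i] + c(-1, 0, 1)
    a <- (2 * v)^(1 / 3)
    data.frame(mouse_id = paste0(gsub("[^[:alnum:]]", "", med$group[i]),
                                 "_", 1:3),
               group = med$group[i], day = med$day[i],
               diam_a_mm = a, diam_b_mm = a, stringsAsFactors = FALSE)
  }))
  s <- summarizeTumorGrowth(
    obs, "vehicle (control)",
    combinations = list(
      "GV + PRI-2191 s.c." = c("GV", "PRI-2191 s.c."),
      "GV + PRI-2191 oral" = c("GV", "PRI-2191 oral")))

  get <- function(col, g, d) s[[col]][s$group == g & s$day == d]
  expect_equal(get("median_volume_mm3", "GV", 21), 486)
  expect_equal(get("tgi_pct", "PRI-2191 s.c.", 14), 36)
  expect_equal(get("tgi_pct", "GV", 21), -6)
  expect_equal(get("htgi_pct", "GV + PRI-2191 s.c.", 14), 45)
  expect_equal(get("htgi_pct", "GV + PRI-2191 oral", 21), 40)
  # control rows carry no TGI/HTGI; single-agent rows no HTGI
  expect_true(all(is.na(s$tgi_pct[s$group == "vehicle (control)"])))
  expect_true(all(is.na(s$htgi_pct[s$group == "GV"])))
})
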