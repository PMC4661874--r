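#' Caliper tumor volume
#'
#' Ellipsoid-approximation volume from two perpendicular caliper
#' diameters: V = (a^2 x b) / 2 with a the shorter and b the longer
#' diameter in mm. Input order is irrelevant; the shorter diameter is
#' squared.
#'
#' @param a,b tumor diameters in mm (> 0, vectorized).
#' @return volumes in mm^3.
#' @examples
#' tumorVolume(6, 8)   # 36 * 8 / 2 = 144
#' tumorVolume(8, 6)   # identical
#' @export
tumorVolume <- function(a, b) {
  if (any(a <= 0 | b <= 0, na.rm = TRUE))
    stop("tumor diameters must be positive", call. = FALSE)
  pmin(a, b)^2 * pmax(a, b) / 2
}

.volumes <- function(observations) {
  stopifnot(all(c("group", "day", "diam_a_mm", "diam_b_mm") %in%
                  names(observations)))
  tumorVolume(observations$diam_a_mm, observations$diam_b_mm)
}

#' Median tumor volume of a group at a day
#'
#' Sample median over the mice measured for that (group, day); even
#' counts average the two central values. Mice lost to follow-up simply
#' drop out of later medians. A missing (group, day) combination returns
#' NA rather than an error.
#'
#' @param observations data.frame of tumor observations (`mouse_id`,
#'   `group`, `day`, `diam_a_mm`, `diam_b_mm`, optional `weight_g`).
#' @param group,day group label and measurement day to summarize.
#' @return median volume in mm^3, or NA when no mice were measured.
#' @export
groupMedian <- function(observations, group, day) {
  sel <- observations$group == group & observations$day == day
  if (!any(sel)) return(NA_real_)
  median(.volumes(observations[sel, , drop = FALSE]))
}

#' Tumor growth inhibition (TGI)
#'
#' Percent reduction of the treated-group median tumor volume relative
#' to the concurrent control: 100 x (1 - VT / VC). Positive values mean
#' inhibition; a treated median above control gives a negative TGI.
#' Reported values are rounded to the nearest integer (half away from
#' zero); pass `round = FALSE` for full precision.
#'
#' @param vt treated-group median volume, mm^3.
#' @param vc control-group median volume, mm^3 (> 0).
#' @param round round to nearest integer for reporting (default TRUE).
#' @return TGI percent (vectorized over `vt`/`vc`).
#' @examples
#' tgi(98, 154)   # 36
#' tgi(486, 460)  # -6
#' @export
tgi <- function(vt, vc, round = TRUE) {
  if (any(vc <= 0, na.rm = TRUE))
    stop("control median volume must be positive", call. = FALSE)
  out <- 100 * (1 - vt / vc)
  if (round) roundHalfOut(out) else out
}

#' Hypothetical TGI under Bliss independence
#'
#' Expected combination TGI if two single agents acted independently on
#' tumor volume: the treated/control volume ratios multiply, so
#' HTGI = 100 x (1 - (VT_A / VC) x (VT_B / VC)). Computed for a
#' combination group from the two single-agent medians; a combination
#' beating its HTGI indicates in vivo synergy. Note the algebraic
#' identity htgi(vA, vB, vc) = tgi(vA * vB / vc, vc).
#'
#' @param vtA,vtB single-agent median volumes, mm^3.
#' @param vc control median volume, mm^3 (> 0).
#' @param round round to nearest integer for reporting (default TRUE).
#' @return hypothetical TGI percent.
#' @examples
#' htgi(98, 134, 154)   # 45
#' htgi(263, 486, 460)  # 40
#' @export
htgi <- function(vtA, vtB, vc, round = TRUE) {
  if (any(vc <= 0, na.rm = TRUE))
    stop("control median volume must be positive", call. = FALSE)
  out <- 100 * (1 - (vtA / vc) * (vtB / vc))
  if (round) roundHalfOut(out) else out
}

#' Mean body-weight change from baseline
#'
#' Percent change of mean body weight between a baseline day (treatment
#' start) and a target day, over the mice weighed on both days:
#' 100 x (mean(day) - mean(baseline)) / mean(baseline).
#'
#' @param observations tumor-observation data.frame including `weight_g`.
#' @param group group label.
#' @param day target day.
#' @param baselineDay baseline day (default: the group's first day).
#' @return percent change, or NA when no mouse was weighed on both days.
#' @export
bodyWeightChange <- function(observations, group, day, baselineDay = NULL) {
  stopifnot("weight_g" %in% names(observations))
  g <- observations[observations$group == group, , drop = FALSE]
  if (is.null(baselineDay)) baselineDay <- min(g$day)
  atBase <- g[g$day == baselineDay & !is.na(g$weight_g), ]
  atDay <- g[g$day == day & !is.na(g$weight_g), ]
  shared <- intersect(atBase$mouse_id, atDay$mouse_id)
  if (!length(shared)) return(NA_real_)
  mb <- mean(atBase$weight_g[match(shared, atBase$mouse_id)])
  md <- mean(atDay$weight_g[match(shared, atDay$mouse_id)])
  100 * (md - mb) / mb
}

#' Nonparametric comparison of two groups' tumor volumes at a day
#'
#' Two-tailed rank-based comparison of per-mouse volumes, delegated to
#' the standard tests: Mann-Whitney / Wilcoxon rank-sum (default) or
#' Kruskal-Wallis. Significance is conventionally read at p < 0.05.
#'
#' @param observations tumor-observation data.frame.
#' @param groupA,groupB group labels to compare.
#' @param day measurement day.
#' @param test `"wilcoxon"` (default) or `"kruskal"`.
#' @return two-tailed p-value, or NA when either group has < 2 mice.
#' @export
compareGroups <- function(observations, groupA, groupB, day,
                          test = c("wilcoxon", "kruskal")) {
  test <- match.arg(test)
  va <- .volumes(observations[observations$group == groupA &
                                observations$day == day, , drop = FALSE])
  vb <- .volumes(observations[observations$group == groupB &
                                observations$day == day, , drop = FALSE])
  if (length(va) < 2L || length(vb) < 2L) return(NA_real_)
  if (test == "wilcoxon")
    suppressWarnings(wilcox.test(va, vb, alternative = "two.sided"))$p.value
  else
    kruskal.test(list(va, vb))$p.value
}

#' Group-by-day efficacy summary (volume medians, TGI, hypothetical TGI)
#'
#' Builds the standard xenograft efficacy table: per group and day the
#' number of mice, median tumor volume, TGI relative to the control
#' group, body-weight change from baseline, and — for combination groups
#' with declared single-agent partners — the hypothetical TGI expected
#' under independence. TGI is computed only for days on which both the
#' group and the control were measured; no interpolation across days.
#'
#' @param observations tumor-observation data.frame.
#' @param controlGroup label of the untreated control group.
#' @param combinations named list mapping a combination-group label to
#'   the character vector of its two single-agent group labels, e.g.
#'   `list("GV + PRI-2191 s.c." = c("GV", "PRI-2191 s.c."))`.
#' @param days days to tabulate (default: all observed days).
#' @param baselineDay baseline for body-weight change (default: first
#'   observed day).
#' @return data.frame with columns `group`, `day`, `n_mice`,
#'   `median_volume_mm3`, `tgi_pct`, `htgi_pct`,
#'   `body_weight_change_pct`. TGI/HTGI are reported rounded to integer;
#'   the control rows carry NA ("countless") in both.
#' @export
summarizeTumorGrowth <- function(observations, controlGroup,
                                 combinations = list(), days = NULL,
                                 baselineDay = NULL) {
  stopifnot(controlGroup %in% observations$group)
  if (is.null(days)) days <- sort(unique(observations$day))
  if (is.null(baselineDay)) baselineDay <- min(observations$day)
  groups <- unique(observations$group)
  hasWeight <- "weight_g" %in% names(observations)

  rows <- list()
  for (d in days) {
    vc <- groupMedian(observations, controlGroup, d)
    for (g in groups) {
      sel <- observations$group == g & observations$day == d
      n <- length(unique(observations$mouse_id[sel]))
      if (n == 0L) next
      vm <- groupMedian(observations, g, d)
      t <- if (g != controlGroup && !is.na(vc)) tgi(vm, vc) else NA_real_
      h <- NA_real_
      if (g %in% names(combinations) && !is.na(vc)) {
        partners <- combinations[[g]]
        stopifnot(length(partners) == 2L)
        vA <- groupMedian(observations, partners[1], d)
        vB <- groupMedian(observations, partners[2], d)
        if (!is.na(vA) && !is.na(vB)) h <- htgi(vA, vB, vc)
      }
      bw <- if (hasWeight) bodyWeightChange(observations, g, d, baselineDay)
            else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, day = d, n_mice = n, median_volume_mm3 = vm,
        tgi_pct = t, htgi_pct = h, body_weight_change_pct = bw,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
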