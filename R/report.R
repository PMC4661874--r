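#' Read and validate a pipeline run configuration
#'
#' YAML-backed configuration for the command-line pipeline. Recognized
#' keys: `mode` (simulate / ic50 / ci / invivo / full), input paths
#' (`plate_csv`, `animal_csv`, `ci_grid_csv`), `out_dir`, `ic50_method`
#' ("interpolation" or "4pl"), `effect_level` (F in (0,1), default 0.5),
#' `ci_thresholds` (two numbers, default 0.8 and 1.2), `plot_call_tolerance`
#' (default 0.05), `seed` (required for simulate), `control_group`,
#' `combinations` (map combination group -> two single-agent groups).
#'
#' @param path YAML file path.
#' @return validated named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$mode) ||
      !cfg$mode %in% c("simulate", "ic50", "ci", "invivo", "full"))
    stop("config: 'mode' must be one of simulate/ic50/ci/invivo/full",
         call. = FALSE)
  cfg$ic50_method <- cfg$ic50_method %||% "interpolation"
  if (!cfg$ic50_method %in% c("interpolation", "4pl"))
    stop("config: ic50_method must be 'interpolation' or '4pl'",
         call. = FALSE)
  cfg$effect_level <- cfg$effect_level %||% 0.5
  if (cfg$effect_level <= 0 || cfg$effect_level >= 1)
    stop("config: effect_level must lie in (0, 1)", call. = FALSE)
  cfg$ci_thresholds <- unlist(cfg$ci_thresholds %||% c(0.8, 1.2))
  if (length(cfg$ci_thresholds) != 2L ||
      cfg$ci_thresholds[1] >= cfg$ci_thresholds[2])
    stop("config: ci_thresholds must be two numbers, lower < upper",
         call. = FALSE)
  cfg$plot_call_tolerance <- cfg$plot_call_tolerance %||% 0.05
  if (cfg$mode %in% c("simulate", "full") && is.null(cfg$seed))
    stop("config: 'seed' is required for simulate/full mode", call. = FALSE)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.ic50Row <- function(e) {
  data.frame(condition = conditionLabel(e),
             varied_agent = e@variedAgent,
             background = formatBackground(e@background),
             method = e@method, status = e@status,
             n_experiments = length(e@perExperiment),
             n_excluded = e@nExcluded,
             ic50_mean = e@mean, ic50_sd = e@sd,
             dose_unit = e@doseUnit,
             flags = paste(e@flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Render analysis results to CSV + JSON report files
#'
#' Writes the pipeline's result tables in both CSV and JSON mirrors:
#' an IC50 table (one row per condition: mean, SD, method, status), a
#' combination-index table in the screen's grid shape (undefined CIs
#' rendered as `"countless"` in the CSV, `null` in the JSON), and the
#' in vivo efficacy table from [summarizeTumorGrowth()]. A `notes`
#' field records the methodological flags a reader needs: the IC50
#' method used, the CI thresholds, the HTGI definition (independence
#' expectation), the TGI sign convention, and any data-quality flags
#' raised upstream. Empty sections are omitted.
#'
#' @param ic50Results list of aggregated [IC50Estimate-class] objects,
#'   or NULL.
#' @param ciResults data.frame from [ciGrid()], or NULL.
#' @param invivoSummary data.frame from [summarizeTumorGrowth()], or NULL.
#' @param outDir output directory (created if needed).
#' @param thresholds CI classification thresholds used (recorded in the
#'   notes).
#' @return invisible character vector of the files written.
#' @export
renderReport <- function(ic50Results = NULL, ciResults = NULL,
                         invivoSummary = NULL, outDir = ".",
                         thresholds = c(0.8, 1.2)) {
  if (is.null(ic50Results) && is.null(ciResults) && is.null(invivoSummary))
    stop("no analysis results to render", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  notes <- character()
  payload <- list()

  if (!is.null(ic50Results)) {
    if (is(ic50Results, "IC50Estimate")) ic50Results <- list(ic50Results)
    tab <- do.call(rbind, lapply(ic50Results, .ic50Row))
    f <- file.path(outDir, "ic50_table.csv")
    utils::write.csv(tab, f, row.names = FALSE, fileEncoding = "UTF-8")
    written <- c(written, f)
    payload$ic50 <- tab
    notes <- c(notes,
               paste0("IC50 method(s): ",
                      paste(unique(tab$method), collapse = ", "),
                      "; mean and sample (n-1) SD over ok-status experiments."),
               if (any(tab$status != "ok"))
                 "Some IC50s fell outside the tested dose range (see status).")
    fl <- setdiff(unique(unlist(strsplit(tab$flags, ";"))), "")
    if (length(fl))
      notes <- c(notes, paste0("IC50 flags raised: ",
                               paste(fl, collapse = ", "), "."))
  }

  if (!is.null(ciResults)) {
    tab <- as.data.frame(ciResults)
    tab$ci_rendered <- ifelse(is.na(tab$ci), "countless",
                              formatC(tab$ci, digits = 3, format = "f"))
    f <- file.path(outDir, "combination_index_table.csv")
    utils::write.csv(tab, f, row.names = FALSE, fileEncoding = "UTF-8")
    written <- c(written, f)
    payload$combination_index <- tab
    notes <- c(notes,
               sprintf(paste0("Mutually non-exclusive combination index at ",
                              "IC50; CI < %g synergism, CI > %g antagonism, ",
                              "%g-%g additive (boundaries additive); ",
                              "undefined CI rendered 'countless'."),
                       thresholds[1], thresholds[2], thresholds[1],
                       thresholds[2]))
  }

  if (!is.null(invivoSummary)) {
    f <- file.path(outDir, "invivo_efficacy_table.csv")
    utils::write.csv(invivoSummary, f, row.names = FALSE,
                     fileEncoding = "UTF-8")
    written <- c(written, f)
    payload$invivo <- invivoSummary
    notes <- c(notes,
               paste0("TGI = 100*(1 - VT/VC), positive = inhibition ",
                      "(sign flipped relative to the literal (VT/VC)*100 - 100% ",
                      "formula so that inhibition reads positive)."),
               paste0("HTGI is the hypothetical TGI under independence: ",
                      "100*(1 - (VT_A/VC)*(VT_B/VC)) from the two ",
                      "single-agent medians."))
  }

  payload$notes <- notes
  fj <- file.path(outDir, "report.json")
  jsonlite::write_json(payload, fj, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, fj)

  ft <- file.path(outDir, "report_notes.txt")
  writeLines(notes, ft)
  written <- c(written, ft)
  invisible(written)
}
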