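## CSV dialect: UTF-8, comma-separated, dot decimal, mandatory header.
## Animal columns carry units in their names (diam_a_mm, weight_g); plate
## doses carry a per-row dose_unit column because one file may mix agents
## with different native units (ng/mL cytostatics vs nM analogs).

.plateCols <- c("experiment_id", "varied_agent", "dose", "dose_unit",
                "background", "replicate", "viability")
.animalCols <- c("mouse_id", "group", "day", "diam_a_mm", "diam_b_mm")

.readTable <- function(path, mandatory) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("cannot parse CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L && ncol(df) == 0L)
    stop("empty file: ", path, call. = FALSE)
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("'", path, "' lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

## coerce columns to numeric, collecting 1-based data-row numbers of
## rows that fail; malformed rows are dropped, reported via attribute
.dropMalformed <- function(df, numericCols, positiveCols = character()) {
  bad <- rep(FALSE, nrow(df))
  for (cl in numericCols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- bad | is.na(v)
    df[[cl]] <- v
  }
  for (cl in positiveCols) bad <- bad | (!is.na(df[[cl]]) & df[[cl]] <= 0)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "problems") <- which(bad)
  if (any(bad))
    warning(sum(bad), " malformed row(s) dropped (data rows: ",
            paste(which(bad), collapse = ", "), ")", call. = FALSE)
  out
}

#' Read / write the plate-well CSV dialect
#'
#' One row per well with columns `experiment_id`, `varied_agent`, `dose`,
#' `dose_unit`, `background`, `replicate`, `viability` (fraction of
#' vehicle control). Malformed data rows (non-numeric dose/viability,
#' negative dose) are dropped with a warning and their 1-based data-row
#' numbers attached as attribute `"problems"`. Write-then-read is an
#' identity on well records.
#'
#' @param path CSV file path.
#' @return `readPlateCsv()`: a well-record data.frame.
#'   `writePlateCsv()`: `path`, invisibly.
#' @export
readPlateCsv <- function(path) {
  df <- .readTable(path, .plateCols)
  df$background[is.na(df$background)] <- ""
  df <- .dropMalformed(df, c("dose", "replicate", "viability"))
  probs <- attr(df, "problems")
  if (any(df$dose < 0) || any(df$viability < 0)) {
    keep <- df$dose >= 0 & df$viability >= 0
    warning(sum(!keep), " row(s) with negative dose/viability dropped",
            call. = FALSE)
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  out <- df[.plateCols]
  if (length(probs)) attr(out, "problems") <- probs
  out
}

#' @rdname readPlateCsv
#' @param wells well-record data.frame (see [simulatePlate()]).
#' @export
writePlateCsv <- function(wells, path) {
  stopifnot(all(.plateCols %in% names(wells)))
  utils::write.csv(wells[.plateCols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write the animal-study CSV dialect
#'
#' One row per mouse per measurement day with columns `mouse_id`,
#' `group`, `day`, `diam_a_mm`, `diam_b_mm` and optional `weight_g`.
#' Diameters are canonicalized on read so that `diam_a_mm <= diam_b_mm`
#' (a is the shorter caliper diameter); malformed rows are dropped with
#' a warning as in [readPlateCsv()]. A missing weight column is
#' tolerated (weights are optional).
#'
#' @param path CSV file path.
#' @return `readAnimalCsv()`: a tumor-observation data.frame.
#'   `writeAnimalCsv()`: `path`, invisibly.
#' @export
readAnimalCsv <- function(path) {
  df <- .readTable(path, .animalCols)
  hasWeight <- "weight_g" %in% names(df)
  num <- c("day", "diam_a_mm", "diam_b_mm")
  df <- .dropMalformed(df, num, positiveCols = c("diam_a_mm", "diam_b_mm"))
  if (hasWeight) df$weight_g <- suppressWarnings(as.numeric(df$weight_g))
  swap <- df$diam_a_mm > df$diam_b_mm
  if (any(swap)) {
    tmp <- df$diam_a_mm[swap]
    df$diam_a_mm[swap] <- df$diam_b_mm[swap]
    df$diam_b_mm[swap] <- tmp
  }
  cols <- c(.animalCols, if (hasWeight) "weight_g")
  out <- df[cols]
  probs <- attr(df, "problems")
  if (length(probs)) attr(out, "problems") <- probs
  out
}

#' @rdname readAnimalCsv
#' @param observations tumor-observation data.frame (see
#'   [simulateTumorStudy()]).
#' @export
writeAnimalCsv <- function(observations, path) {
  stopifnot(all(.animalCols %in% names(observations)))
  cols <- c(.animalCols,
            if ("weight_g" %in% names(observations)) "weight_g")
  utils::write.csv(observations[cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Published A549 xenograft median tumor volumes
#'
#' The study-reported per-group median tumor volumes (mm^3) at Days 14
#' and 21 for the A549 xenograft experiment comparing subcutaneous vs
#' oral vitamin D analog administration with and without imatinib,
#' shipped with the package as the worked in vivo input table. Columns:
#' `group`, `day`, `median_volume_mm3`. The TGI and hypothetical-TGI
#' columns of the published table are *not* stored; they are recomputed
#' by [tgi()] / [htgi()].
#'
#' @return data.frame of group/day median volumes.
#' @examples
#' med <- a549MedianVolumes()
#' with(med, tgi(median_volume_mm3[group == "PRI-2191 s.c." & day == 14],
#'               median_volume_mm3[group == "vehicle (control)" & day == 14]))
#' @export
a549MedianVolumes <- function() {
  path <- system.file("extdata", "a549_xenograft_medians.csv",
                      package = "comboEff", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
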