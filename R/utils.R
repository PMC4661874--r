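#' Round half away from zero
#'
#' Reporting convention for TGI/HTGI percentages: nearest integer with ties
#' rounded away from zero (so 44.5 -> 45 and -5.5 -> -6), unlike base
#' [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
roundHalfOut <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Evaluate an expression with a local RNG seed
#'
#' All stochastic operations in the package draw their randomness through
#' this helper: the global RNG state is saved, the given seed installed,
#' and the previous state restored afterwards, so simulation functions are
#' deterministic in their `seed` argument and leave no global side effects.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## lognormal multiplier with mean 1 and coefficient of variation cv
rlnormCV <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Serialize / parse a background-agent specification
#'
#' A background is zero or more agents held at fixed doses while another
#' agent is varied (e.g. a vitamin D analog at 100 nM under an imatinib
#' titration). In flat tables it is carried as a single string of the form
#' `"agent=dose unit"` with multiple agents joined by `"; "`; an empty
#' string means no background.
#'
#' @param background data.frame with columns `agent`, `dose`, `unit`.
#' @return `formatBackground()`: a single string. `parseBackground()`: a
#'   data.frame with columns `agent`, `dose`, `unit` (zero rows for "").
#' @examples
#' formatBackground(data.frame(agent = "PRI-2191", dose = 100, unit = "nM"))
#' parseBackground("PRI-2191=100 nM")
#' @export
formatBackground <- function(background) {
  if (is.null(background) || nrow(background) == 0L) return("")
  stopifnot(all(c("agent", "dose", "unit") %in% names(background)))
  paste(sprintf("%s=%s %s", background$agent,
                format(background$dose, trim = TRUE, scientific = FALSE),
                background$unit),
        collapse = "; ")
}

#' @rdname formatBackground
#' @param x a background string such as `"PRI-2191=100 nM"`.
#' @export
parseBackground <- function(x) {
  empty <- data.frame(agent = character(), dose = numeric(),
                      unit = character(), stringsAsFactors = FALSE)
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(trimws(x)))
    return(empty)
  parts <- strsplit(trimws(x), ";")[[1]]
  out <- lapply(parts, function(p) {
    p <- trimws(p)
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed background entry: '", p, "'", call. = FALSE)
    dv <- strsplit(trimws(kv[2]), "[[:space:]]+")[[1]]
    dose <- suppressWarnings(as.numeric(dv[1]))
    if (is.na(dose))
      stop("malformed background dose in: '", p, "'", call. = FALSE)
    data.frame(agent = trimws(kv[1]), dose = dose,
               unit = if (length(dv) > 1L) paste(dv[-1], collapse = " ") else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
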