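#' Dinucleotide twist-fluctuation step tables
#'
#' A step table assigns to each of the 16 dinucleotide steps (AA, AC, ..., TT)
#' the magnitude of the thermal fluctuation of the helical twist angle at that
#' step, in degrees. Because the two strands describe the same double helix,
#' the table must be symmetric under reverse complementation:
#' \code{value(XY) == value(revcomp(XY))} (AA == TT, AC == GT, ...), leaving
#' 10 free parameters.
#'
#' @param path Path to a tab- or whitespace-separated file with a header line
#'   and two columns, \code{step} and \code{value} (degrees). Either all 16
#'   steps or only the 10 unique-under-complement steps may be listed; missing
#'   complements are filled in by symmetry.
#' @return A named numeric vector of length 16 (class \code{"step_table"}),
#'   ordered AA, AC, ..., TT.
#' @details Values must be strictly positive and any explicitly listed
#'   complement pair must agree to within 1e-9 degrees; violations are errors.
#' @examples
#' tab <- default_step_table()
#' range(tab)
#' @export
load_step_table <- function(path) {
  if (!file.exists(path)) .stopf("step table file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("step", "value") %in% names(df)))
    .stopf("step table needs columns 'step' and 'value': %s", path)
  df$step <- toupper(df$step)
  bad <- setdiff(df$step, DINUC_STEPS)
  if (length(bad)) .stopf("unknown dinucleotide step(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(df$step)) .stopf("duplicated step in table: %s", path)
  step_table(stats::setNames(df$value, df$step))
}

#' @param values Named numeric vector mapping steps to degrees (16 entries or
#'   the 10 unique-under-complement ones).
#' @rdname load_step_table
#' @export
step_table <- function(values) {
  if (is.null(names(values))) .stopf("step values must be named by dinucleotide")
  nm <- toupper(names(values))
  bad <- setdiff(nm, DINUC_STEPS)
  if (length(bad)) .stopf("unknown dinucleotide step(s): %s", paste(bad, collapse = ", "))
  v <- stats::setNames(rep(NA_real_, 16L), DINUC_STEPS)
  v[nm] <- as.numeric(values)
  # symmetry of explicitly listed complement pairs first
  for (s in DINUC_STEPS) {
    rc <- revcomp_step(s)
    if (!is.na(v[s]) && !is.na(v[rc]) && abs(v[s] - v[rc]) > 1e-9)
      .stopf("reverse-complement symmetry violated: %s=%g vs %s=%g",
             s, v[s], rc, v[rc])
  }
  for (s in DINUC_STEPS) {            # fill missing complements
    rc <- revcomp_step(s)
    if (is.na(v[s]) && !is.na(v[rc])) v[s] <- v[rc]
  }
  if (anyNA(v))
    .stopf("step table incomplete; missing: %s",
           paste(DINUC_STEPS[is.na(v)], collapse = ", "))
  if (any(v <= 0)) .stopf("step values must be positive")
  structure(v, class = c("step_table", "numeric"))
}

#' @rdname load_step_table
#' @details \code{default_step_table()} loads the table shipped with the
#'   package, \code{inst/extdata/twist_fluctuation_steps_synthetic.tsv}. The
#'   published dinucleotide twist-fluctuation parameters behind historical
#'   flexibility profilers are not redistributable here, so the shipped table
#'   is a \emph{synthetic} reconstruction: it preserves the established
#'   qualitative ordering (TA by far the most flexible step, G+C-only steps
#'   the stiffest), reverse-complement symmetry, and a min/max that brackets
#'   the [7, 16] degree range of genome window values. Analyses intended to
#'   reproduce published genome-wide numbers should load the original
#'   parameter set with \code{load_step_table()} instead.
#' @export
default_step_table <- function() {
  path <- system.file("extdata", "twist_fluctuation_steps_synthetic.tsv",
                      package = "twistflexr", mustWork = TRUE)
  load_step_table(path)
}

#' @export
print.step_table <- function(x, ...) {
  cat("Dinucleotide twist-fluctuation table (deg):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
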