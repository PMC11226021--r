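# Shared helpers: name normalization, unit-mass rounding, error classes.

#' Normalize a chemical name for lookup
#'
#' Trims, collapses internal whitespace and case-folds. Chemically
#' meaningful punctuation (commas, stereodescriptors such as ", (Z)-") is
#' kept: only whitespace and case are normalized, so vendor exports and
#' reference stores agree on the same key.
#'
#' @param x character vector of chemical names.
#' @return character vector of normalized keys.
#' @export
#' @examples
#' normalize_name("  Methyl  Salicylate ")
normalize_name <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Round m/z values to unit mass
#'
#' Round-half-up to the nearest integer, the single-quadrupole convention
#' for nominal-mass comparison of fragment m/z values. (`round()` in R is
#' round-half-even, which would send 42.5 to 42.)
#'
#' @param mz numeric vector of m/z values.
#' @return integer vector.
#' @export
unit_mass <- function(mz) as.integer(floor(mz + 0.5))

# stop() with a subclass so callers/tests can distinguish contract failures
mz_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "mzexacto_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric formatting used by all CSV writers: full precision, plain notation,
# deterministic across platforms
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    s
  }, character(1))
  out
}
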