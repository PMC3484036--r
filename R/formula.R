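#' Parse an elemental formula into element counts
#'
#' Parses a Hill-style elemental formula string (e.g. `"C6H12O6"`) into a
#' named integer vector of element counts. Repeated element runs are summed,
#' so `"CH3COOH"` parses to `c(C = 2, H = 4, O = 2)`.
#'
#' @param formula A single formula string. Element symbols are one capital
#'   letter optionally followed by one lowercase letter; counts are optional
#'   (defaulting to 1).
#' @return A named integer vector of element counts. The empty string and
#'   `NA` return an empty vector (a species with no tracked elements).
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("`formula` must be a single string", call. = FALSE)
  if (is.na(formula) || !nzchar(formula)) {
    return(stats::setNames(integer(0), character(0)))
  }
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("malformed elemental formula: '", formula, "'", call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  sums <- tapply(counts, elems, sum)[unique(elems)]
  stats::setNames(as.integer(sums), names(sums))
}

#' Count carbon atoms in an elemental formula
#'
#' Returns the stoichiometric number of carbon atoms per molecule, the
#' quantity used for all carbon-yield bookkeeping (glucose has 6 carbons per
#' mole, maltohexaose 36).
#'
#' @inheritParams parse_formula
#' @return A nonnegative integer.
#' @examples
#' carbon_count("C6H12O6") # 6
#' carbon_count("H2O")     # 0
#' @export
carbon_count <- function(formula) {
  counts <- parse_formula(formula)
  n <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  as.integer(n)
}

# NULL/NA-coalescing helper (scalar-oriented; used for optional attributes)
`%||%` <- function(x, y) {
  if (is.null(x)) return(y)
  if (is.atomic(x) && length(x) == 1L && is.na(x)) return(y)
  x
}
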