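#' Parse an elemental formula string
#'
#' Formulas are Hill-style strings over the supported elements C, H, N, O, S
#' with positive integer counts, e.g. `"C4H7NO2"` for the threonine residue.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1, !is.na(formula))
  s <- gsub("\\s", "", formula)
  if (!nzchar(s)) stop("empty formula", call. = FALSE)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("malformed formula: '", formula, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  bad <- setdiff(el, names(ATOMIC_MASS))
  if (length(bad) > 0) {
    stop("unsupported element symbol: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(n, factor(el, levels = names(ATOMIC_MASS)), sum)
  counts <- counts[!is.na(counts)]
  storage.mode(counts) <- "integer"
  if (any(counts <= 0L)) stop("element counts must be positive", call. = FALSE)
  counts
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula A formula string (see [parse_formula()]) or a named count
#'   vector over the supported elements.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("H2O")        # 18.01056
#' formula_mass("C6H10N2O3")  # fOHOrn residue, 158.0691
#' @export
formula_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else {
    bad <- setdiff(names(formula), names(ATOMIC_MASS))
    if (length(bad) > 0) {
      stop("unsupported element symbol: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (length(formula) == 0) stop("empty formula", call. = FALSE)
    formula
  }
  sum(ATOMIC_MASS[names(counts)] * as.numeric(counts))
}
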