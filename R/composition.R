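# Elemental compositions: a light S3 wrapper around a named integer vector.

#' Create an elemental composition
#'
#' An elemental composition is a named non-negative integer vector of atom
#' counts, restricted to the elements in the embedded isotope table.
#' Zero counts are dropped.
#'
#' @param counts Named numeric/integer vector, e.g. `c(C = 6, H = 12, O = 6)`.
#' @return An object of class `elem_comp`.
#' @export
elem_comp <- function(counts = integer(0)) {
  if (length(counts) == 0) {
    x <- integer(0)
    names(x) <- character(0)
    return(structure(x, class = "elem_comp"))
  }
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("composition counts must be named by element symbol")
  bad <- setdiff(names(counts), names(.ISOTOPES))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0))
    stop("negative atom count in composition")
  if (any(counts != round(counts)))
    stop("atom counts must be integers")
  counts <- counts[counts > 0]
  # canonical element order: table order (CHNOSP)
  counts <- counts[order(match(names(counts), names(.ISOTOPES)))]
  structure(as.integer(counts), names = names(counts), class = "elem_comp")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat("<elem_comp> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Parse a chemical formula
#'
#' Parses Hill-like notation such as `"C6H12O6"` into an elemental
#' composition. Counts default to 1 when omitted; zero counts are dropped;
#' repeated element tokens accumulate.
#'
#' @param text A formula string.
#' @return An [elem_comp] object.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C34H53N9O15")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    stop("formula must be a single string")
  s <- gsub("[[:space:]]", "", text)
  if (s == "") return(elem_comp())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("malformed formula: ", text)
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    nstr <- sub("^[A-Za-z]+", "", tok)
    n <- if (nstr == "") 1L else as.integer(nstr)
    if (!el %in% names(.ISOTOPES))
      stop("unknown element symbol: ", el)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  elem_comp(counts)
}

#' Format an elemental composition as a formula string
#'
#' Inverse of [parse_formula()] (up to canonical CHNOSP element order).
#'
#' @param comp An [elem_comp] object.
#' @return A single string; `""` for the empty composition.
#' @export
format_formula <- function(comp) {
  stopifnot(inherits(comp, "elem_comp"))
  if (length(comp) == 0) return("")
  paste0(names(comp), ifelse(comp == 1, "", comp), collapse = "")
}

#' Add two elemental compositions
#' @param a,b [elem_comp] objects.
#' @return Their sum as an [elem_comp].
#' @export
comp_add <- function(a, b) {
  els <- union(names(a), names(b))
  v <- vapply(els, function(el) {
    (if (el %in% names(a)) a[[el]] else 0L) +
      (if (el %in% names(b)) b[[el]] else 0L)
  }, integer(1))
  names(v) <- els
  elem_comp(v)
}

#' Subtract one elemental composition from another
#'
#' Errors if any resulting count would be negative.
#' @param a,b [elem_comp] objects.
#' @return `a - b` as an [elem_comp].
#' @export
comp_subtract <- function(a, b) {
  els <- union(names(a), names(b))
  v <- vapply(els, function(el) {
    (if (el %in% names(a)) a[[el]] else 0L) -
      (if (el %in% names(b)) b[[el]] else 0L)
  }, integer(1))
  if (any(v < 0))
    stop("composition subtraction yields negative count for: ",
         paste(els[v < 0], collapse = ", "))
  names(v) <- els
  elem_comp(v)
}

#' Monoisotopic mass of a composition
#'
#' Sum of the lightest-isotope masses over all atoms.
#' @param comp An [elem_comp] object.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  stopifnot(inherits(comp, "elem_comp"))
  if (length(comp) == 0) return(0)
  sum(vapply(names(comp), function(el) {
    .ISOTOPES[[el]]$mass[1] * comp[[el]]
  }, numeric(1)))
}

#' Total atom count of a composition
#' @param comp An [elem_comp] object.
#' @return Integer atom count.
#' @export
atom_count <- function(comp) {
  stopifnot(inherits(comp, "elem_comp"))
  sum(comp)
}
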