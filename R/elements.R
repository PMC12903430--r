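#' Atomic mass tables
#'
#' Standard (abridged IUPAC) atomic weights and principal-isotope
#' (monoisotopic) masses for the elements the dendrimer chemistry uses,
#' plus a few common extras.  Values in g/mol.
#'
#' @format Named numeric vectors, one entry per element symbol.
#' @name atomic_masses
#' @keywords internal
NULL

.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Br = 79.904, I = 126.904
)

.monoisotopic <- c(
  H = 1.00782503207, C = 12, N = 14.0030740048, O = 15.9949146196,
  F = 18.99840322, Na = 22.9897692809, Si = 27.9769265325,
  P = 30.97376163, S = 31.97207100, Cl = 34.96885268,
  K = 38.96370668, Br = 78.9183371, I = 126.904473
)

#' Create an elemental composition
#'
#' A composition is a named vector of non-negative integer atom counts,
#' e.g. `composition(C = 19, H = 26, O = 3, Si = 1)`.  Compositions add and
#' subtract element-wise; subtraction that would drive any count negative
#' is an error, because a molecular fragment cannot contain a negative
#' number of atoms.
#'
#' @param ... Atom counts by element symbol, or a single named vector.
#' @return An object of class `"composition"`.
#' @examples
#' ab3 <- composition(C = 19, H = 26, O = 3, Si = 1)
#' average_mass(ab3)            # 330.5 g/mol
#' ab3 + composition(H = 2, O = 1)
#' @export
composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1L]])))
    counts <- args[[1L]]
  else
    counts <- unlist(args)
  if (length(counts) == 0L) counts <- numeric(0)
  if (is.null(names(counts)) && length(counts) > 0L)
    stop("composition counts must be named by element symbol", call. = FALSE)
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown) > 0L)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(counts < 0))
    stop("atom counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts)))
    stop("atom counts must be integers", call. = FALSE)
  # collapse duplicate symbols, canonical Hill order
  counts <- tapply(counts, names(counts), sum)
  as_composition(setNames(as.vector(counts), names(counts)))
}

# canonicalise a named count vector: Hill order (C, H, then alphabetical)
as_composition <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0L)
    return(structure(numeric(0), class = "composition"))
  syms <- names(counts)
  ordered <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  structure(as.double(counts[ordered]), names = ordered, class = "composition")
}

#' Parse a molecular formula in Hill notation
#'
#' Accepts formulas such as `"C19H26O3Si"`. Dot-separated adduct parts
#' (`"C2H7NS.HCl"`) are summed, so hydrochloride salts can be written the
#' way chemists print them.
#'
#' @param x A formula string.
#' @return A [composition()].
#' @examples
#' parse_formula("C2H7NS.HCl")   # cysteamine hydrochloride
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  total <- structure(numeric(0), class = "composition")
  for (part in strsplit(x, ".", fixed = TRUE)[[1L]]) {
    if (!grepl("^([A-Z][a-z]?[0-9]*)+$", part))
      stop("malformed formula: '", part, "'", call. = FALSE)
    m <- gregexpr("[A-Z][a-z]?[0-9]*", part)[[1L]]
    toks <- regmatches(part, list(m))[[1L]]
    counts <- numeric(0)
    for (tok in toks) {
      sym <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.numeric(n) else 1
      counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + n
    }
    total <- total + composition(counts)
  }
  total
}

#' @export
`+.composition` <- function(e1, e2) {
  syms <- union(names(e1), names(e2))
  out <- setNames(numeric(length(syms)), syms)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  as_composition(out)
}

#' @export
`-.composition` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is undefined for compositions", call. = FALSE)
  syms <- union(names(e1), names(e2))
  out <- setNames(numeric(length(syms)), syms)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] - unclass(e2)
  if (any(out < 0))
    stop("composition subtraction would give negative atom count for: ",
         paste(syms[out < 0], collapse = ", "), call. = FALSE)
  as_composition(out)
}

#' @export
`*.composition` <- function(e1, e2) {
  if (inherits(e1, "composition")) { comp <- e1; k <- e2 } else { comp <- e2; k <- e1 }
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0, k == round(k))
  as_composition(setNames(unclass(comp) * k, names(comp)))
}

#' @export
format.composition <- function(x, ...) {
  if (length(x) == 0L) return("(empty)")
  paste0(names(x), ifelse(unclass(x) == 1, "", unclass(x)), collapse = "")
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> ", format(x), "  (", round(average_mass(x), 3),
      " g/mol)\n", sep = "")
  invisible(x)
}

#' @export
as.character.composition <- function(x, ...) format(x)

#' Average (standard-atomic-weight) mass of a composition
#'
#' @param x A [composition()] or an object with an
#'   [elemental_composition()] method (building block or dendrimer spec).
#' @return Mass in g/mol.
#' @export
average_mass <- function(x) {
  if (!inherits(x, "composition")) x <- elemental_composition(x)
  sum(unclass(x) * .atomic_weights[names(x)])
}

#' Monoisotopic (principal-isotope) mass of a composition
#'
#' @inheritParams average_mass
#' @return Mass in g/mol (Da).
#' @export
monoisotopic_mass <- function(x) {
  if (!inherits(x, "composition")) x <- elemental_composition(x)
  sum(unclass(x) * .monoisotopic[names(x)])
}

#' Atomic weight of a single element
#' @param symbol Element symbol, e.g. `"Si"`.
#' @keywords internal
atomic_weight <- function(symbol) {
  if (!symbol %in% names(.atomic_weights))
    stop("unknown element symbol: ", symbol, call. = FALSE)
  .atomic_weights[[symbol]]
}

# frequently used small molecules
.H2O <- function() composition(H = 2, O = 1)
.HCl <- function() composition(H = 1, Cl = 1)
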