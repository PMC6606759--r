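# package-local cache for the isotope table
.pyc_env <- new.env(parent = emptyenv())

#' Proton mass in daltons
#'
#' Mass of the proton, the charge carrier used for adduct arithmetic
#' (e.g. \[M+H\]+ m/z = neutral mass + one proton). Note this is the mass
#' of H+ (no electron), not of a neutral hydrogen atom.
#'
#' @format A length-one numeric, in Da.
#' @export
proton_mass <- 1.00727646

#' Most-abundant-isotope exact mass table
#'
#' Exact masses (NIST, rounded to eight decimal places) of the most
#' abundant isotope of each element handled by the toolkit: H, C, N, O, S,
#' Se and the thirteen metals of the catalog (Ag, Ca, Cd, Co, Cu, Fe, Hg,
#' Mg, Mn, Ni, Pb, Zn plus Se, which doubles as a bound species).
#' Monoisotopic masses are sums over this table.
#'
#' The table ships with the package as a CSV
#' (\code{system.file("extdata", "isotope_masses.csv", package = "pyctools")})
#' and is cached after the first read.
#'
#' @return A data frame with columns \code{element}, \code{isotope_label}
#'   and \code{exact_mass_da}.
#' @examples
#' head(isotope_masses())
#' @export
isotope_masses <- function() {
  if (is.null(.pyc_env$isotopes)) {
    path <- system.file("extdata", "isotope_masses.csv", package = "pyctools")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("element", "isotope_label", "exact_mass_da") %in% names(tab)))
    # sanity: each exact mass within 0.5 Da of its nominal mass number
    nominal <- as.numeric(sub("[A-Za-z]+$", "", tab$isotope_label))
    stopifnot(all(tab$exact_mass_da > 0), all(abs(tab$exact_mass_da - nominal) < 0.5))
    .pyc_env$isotopes <- tab
    .pyc_env$mass_lookup <- stats::setNames(tab$exact_mass_da, tab$element)
  }
  .pyc_env$isotopes
}

# fast named numeric lookup element -> exact mass
.mass_lookup <- function() {
  isotope_masses()
  .pyc_env$mass_lookup
}

.known_elements <- function() names(.mass_lookup())

#' Parse an elemental formula in Hill notation
#'
#' Converts a formula string such as \code{"C18H29N5O10S2"} to a named
#' integer vector of element counts. Whitespace and underscores (as used
#' in subscript markup) are tolerated and stripped; an omitted count means
#' one atom.
#'
#' @param text A single non-empty formula string.
#' @return A named integer vector of per-element counts in Hill order
#'   (carbon, hydrogen, then all other elements alphabetically).
#' @examples
#' parse_formula("C18H29N5O10S2")
#' parse_formula("H2O")
#' @seealso [format_formula()], [monoisotopic_mass()]
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  clean <- gsub("[[:space:]_]", "", text)
  if (!nzchar(clean)) stop("empty formula string")
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", clean)) {
    # locate the first offending character for the error message
    toks <- gregexpr("[A-Z][a-z]?[0-9]*", clean)[[1]]
    covered <- unlist(mapply(function(s, l) seq(s, s + l - 1L),
                             toks, attr(toks, "match.length"), SIMPLIFY = FALSE))
    bad <- setdiff(seq_len(nchar(clean)), covered)[1]
    if (is.na(bad)) bad <- 1L
    stop(sprintf("malformed formula '%s' at position %d", clean, bad))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", clean)[[1]]
  tokens <- regmatches(clean, list(m))[[1]]
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Z][a-z]?", "", tokens)
  cnts <- ifelse(nzchar(cnts), as.integer(cnts), 1L)
  unknown <- setdiff(syms, .known_elements())
  if (length(unknown)) {
    stop(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")))
  }
  if (any(cnts < 1L)) {
    stop(sprintf("count must be a positive integer for element %s",
                 syms[which(cnts < 1L)[1]]))
  }
  counts <- tapply(cnts, syms, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  .hill_sort(out)
}

# order a named count vector in Hill convention
.hill_sort <- function(counts) {
  counts <- counts[counts != 0L]
  els <- names(counts)
  if ("C" %in% els) {
    first <- intersect(c("C", "H"), els)
    rest <- sort(setdiff(els, first))
    counts[c(first, rest)]
  } else {
    counts[sort(els)]
  }
}

#' Format an elemental formula as a Hill-notation string
#'
#' Inverse of [parse_formula()]: carbon first, hydrogen second, remaining
#' elements (metals included) alphabetically; a count of one is omitted.
#' Formulas without carbon are written in pure alphabetical order.
#'
#' @param f Named integer vector of element counts.
#' @return A single formula string.
#' @examples
#' format_formula(c(C = 18, H = 27, Cd = 1, N = 5, O = 10, S = 2))
#' @export
format_formula <- function(f) {
  f <- .validate_formula(f)
  f <- .hill_sort(f)
  if (!length(f)) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

.validate_formula <- function(f) {
  if (!length(f)) return(integer(0))
  stopifnot(is.numeric(f), !is.null(names(f)), all(nzchar(names(f))))
  if (any(f < 0)) {
    stop(sprintf("negative count for element %s", names(f)[which(f < 0)[1]]))
  }
  stats::setNames(as.integer(f), names(f))[f != 0]
}

#' Element-wise combination of a formula with a signed delta
#'
#' Adds a (possibly negative) count delta to a formula, as used when
#' forming disulfides (subtract 2 H per bond) or metal complexes
#' (subtract thiol protons, add the metal atom). A combination that would
#' drive any element negative is chemically impossible and is rejected.
#'
#' @param f Named integer vector of element counts.
#' @param delta Named integer vector of signed count changes (may be empty).
#' @return The combined formula; elements whose count reaches zero are dropped.
#' @examples
#' combine_formula(parse_formula("C18H29N5O10S2"), c(H = -2))
#' @export
combine_formula <- function(f, delta) {
  f <- .validate_formula(f)
  if (!length(delta)) return(.hill_sort(f))
  stopifnot(is.numeric(delta), !is.null(names(delta)))
  els <- union(names(f), names(delta))
  out <- stats::setNames(integer(length(els)), els)
  out[names(f)] <- f
  out[names(delta)] <- out[names(delta)] + as.integer(delta)
  if (any(out < 0L)) {
    stop(sprintf("combination yields negative count for element %s",
                 els[which(out < 0L)[1]]))
  }
  .hill_sort(out[out != 0L])
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of count times most-abundant-isotope exact mass over the formula's
#' elements. No rounding is applied; rounding to a printed precision is a
#' presentation concern (see [adduct_mz()] users).
#'
#' @param f Named integer vector of element counts (may be empty: mass 0).
#' @param table Isotope table as returned by [isotope_masses()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("C18H29N5O10S2"))
#' @export
monoisotopic_mass <- function(f, table = isotope_masses()) {
  f <- .validate_formula(f)
  if (!length(f)) return(0)
  lookup <- stats::setNames(table$exact_mass_da, table$element)
  missing <- setdiff(names(f), names(lookup))
  if (length(missing)) {
    stop(sprintf("no isotope mass for element(s): %s",
                 paste(missing, collapse = ", ")))
  }
  sum(f * lookup[names(f)])
}
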