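# Accurate-mass annotation: adduct m/z computation, ppm matching and the
# NOPS element-ratio plausibility filter.

.ADDUCTS <- data.frame(
  name = c("M+H", "M+2H", "M+3H", "M+Na", "M+K", "M-H"),
  mass_delta = c(1.00727646, 2 * 1.00727646, 3 * 1.00727646,
                 22.98922070, 38.96315791, -1.00727646),
  z = c(1L, 2L, 3L, 1L, 1L, 1L),
  default = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Adduct registry
#'
#' Ionization adducts available for m/z computation. Deltas are ion
#' masses (proton mass for M+H, not the neutral hydrogen atom; Na+/K+
#' masses are atom minus one electron). M+H, M+2H and M+3H are enabled by
#' default; M+Na, M+K and M-H are available but off by default.
#'
#' @return Data frame with columns \code{name}, \code{mass_delta} (Da),
#'   \code{z} (charge state) and \code{default}.
#' @export
adduct_registry <- function() .ADDUCTS

.resolve_adducts <- function(adducts) {
  if (is.character(adducts)) {
    bad <- setdiff(adducts, .ADDUCTS$name)
    if (length(bad))
      stop(sprintf("unknown adduct(s): %s", paste(bad, collapse = ", ")))
    .ADDUCTS[match(adducts, .ADDUCTS$name), , drop = FALSE]
  } else {
    stopifnot(is.data.frame(adducts),
              all(c("name", "mass_delta", "z") %in% names(adducts)),
              all(adducts$z >= 1L), !anyDuplicated(adducts$name))
    adducts
  }
}

#' Adduct m/z of a neutral mass
#'
#' m/z = (neutral mass + adduct mass delta) / charge state.
#'
#' @param neutral_mass Neutral monoisotopic mass(es) in Da (vectorized).
#' @param adduct Adduct name (see [adduct_registry()]) or a one-row data
#'   frame with \code{mass_delta} and \code{z}.
#' @return m/z value(s).
#' @examples
#' adduct_mz(539.13558, "M+H")  # ~540.1429
#' @export
adduct_mz <- function(neutral_mass, adduct = "M+H") {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  a <- .resolve_adducts(adduct)
  stopifnot(nrow(a) == 1L)
  (neutral_mass + a$mass_delta) / a$z
}

#' Signed ppm mass error
#'
#' 1e6 * (observed - theoretical) / theoretical. Matching uses the
#' absolute value; the theoretical m/z is the denominator, so swapping
#' the arguments changes |ppm| only at the ppm-of-ppm level.
#'
#' @param observed Observed m/z (vectorized).
#' @param theoretical Theoretical m/z (> 0).
#' @return Signed ppm difference(s).
#' @examples
#' ppm_difference(540.1437, 540.1429)  # ~ +1.5
#' @export
ppm_difference <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}

#' NOPS element-ratio rule
#'
#' Maximum plausible ratios of nitrogen, oxygen, phosphorus and sulfur to
#' carbon. Defaults follow the common-range heuristics used in elemental
#' formula filtering of small molecules (N/C <= 1.3, O/C <= 1.2,
#' P/C <= 0.3, S/C <= 0.8); the thresholds are configurable.
#'
#' @param n_c,o_c,p_c,s_c Positive ratio maxima.
#' @return A list of class `nops_rule`.
#' @export
nops_rule <- function(n_c = 1.3, o_c = 1.2, p_c = 0.3, s_c = 0.8) {
  stopifnot(n_c > 0, o_c > 0, p_c > 0, s_c > 0)
  structure(list(n_c = n_c, o_c = o_c, p_c = p_c, s_c = s_c),
            class = "nops_rule")
}

#' NOPS element-ratio check
#'
#' TRUE iff the N/C, O/C, P/C and S/C atom ratios all fall at or below
#' the rule's maxima. Carbon-free formulas fail closed. Bound metals do
#' not enter any ratio.
#'
#' @param f Named integer vector of element counts, or a formula string.
#' @param rule A [nops_rule()].
#' @return Logical.
#' @examples
#' nops_check(parse_formula("C18H29N5O10S2"))
#' @export
nops_check <- function(f, rule = nops_rule()) {
  if (is.character(f)) f <- parse_formula(f)
  f <- .validate_formula(f)
  cnt <- function(e) if (e %in% names(f)) as.numeric(f[[e]]) else 0
  C <- cnt("C")
  if (C == 0) return(FALSE)
  cnt("N") / C <= rule$n_c && cnt("O") / C <= rule$o_c &&
    cnt("P") / C <= rule$p_c && cnt("S") / C <= rule$s_c
}

# vectorized element counts from canonical Hill-notation strings (each
# element appears at most once; a bare symbol means count 1)
.element_counts <- function(strings, elements) {
  out <- matrix(0, length(strings), length(elements),
                dimnames = list(NULL, elements))
  for (e in elements) {
    m <- regexpr(paste0(e, "(?![a-z])([0-9]*)"), strings, perl = TRUE)
    hit <- m > 0
    tok <- substr(strings[hit], m[hit] + nchar(e),
                  m[hit] + attr(m, "match.length")[hit] - 1L)
    out[hit, e] <- ifelse(nzchar(tok), as.numeric(tok), 1)
  }
  out
}

.nops_pass_vec <- function(formulas, rule) {
  cnt <- .element_counts(formulas, c("C", "N", "O", "P", "S"))
  C <- cnt[, "C"]
  C > 0 & cnt[, "N"] <= rule$n_c * C & cnt[, "O"] <= rule$o_c * C &
    cnt[, "P"] <= rule$p_c * C & cnt[, "S"] <= rule$s_c * C
}

#' Annotate experimental masses against a species catalog
#'
#' For every combination of query m/z, catalog species passing the
#' filters, and adduct, reports a match when the absolute ppm difference
#' between the query and the theoretical adduct m/z is at or below the
#' tolerance. All species within tolerance are reported (no best-hit
#' collapsing); matches are ordered by query and then by |ppm|.
#'
#' @param queries Numeric vector of experimental m/z values.
#' @param catalog A `pyc_catalog` (see [enumerate_catalog()]).
#' @param adducts Character vector of adduct names, or a data frame as in
#'   [adduct_registry()]. Must be non-empty.
#' @param tolerance_ppm Positive matching tolerance in ppm (default 5).
#' @param metals Optional character vector: keep only complexes whose
#'   bound metals all belong to this subset (at least one ion bound).
#'   NULL (default) keeps everything, including metal-free species.
#' @param terminals Optional subset of terminal residue labels.
#' @param n_range Optional length-2 integer vector c(min, max) of repeat
#'   counts.
#' @param nops Apply the NOPS element-ratio filter to candidate species
#'   (default FALSE).
#' @param nops_rule Rule used when `nops = TRUE`.
#' @return Data frame with columns `query_mz`, `name`, `formula`,
#'   `adduct`, `theoretical_mz`, `ppm_error`, `terminal`, `n`,
#'   `disulfides`, `metals`, `bridge`.
#' @examples
#' cat2 <- enumerate_catalog(enumeration_config(terminals = "Gly",
#'                                              n_max = 3, max_metals = 0))
#' annotate_masses(538.1270, cat2, adducts = "M+H", tolerance_ppm = 5)
#' @export
annotate_masses <- function(queries, catalog, adducts = "M+H",
                            tolerance_ppm = 5, metals = NULL,
                            terminals = NULL, n_range = NULL,
                            nops = FALSE, nops_rule = pyctools::nops_rule()) {
  if (!length(queries)) stop("queries must be non-empty")
  if (!is.numeric(queries) || anyNA(queries))
    stop("queries must be numeric and free of missing values")
  stopifnot(inherits(catalog, "data.frame"), tolerance_ppm > 0)
  if (!length(adducts)) stop("adduct list must be non-empty")
  adt <- .resolve_adducts(adducts)

  keep <- rep(TRUE, nrow(catalog))
  if (!is.null(metals)) {
    bad <- setdiff(metals, .METALS)
    if (length(bad))
      stop(sprintf("unknown metal symbol(s): %s", paste(bad, collapse = ", ")))
    keep <- keep & catalog$metal1 != "" &
      catalog$metal1 %in% metals &
      (catalog$metal2 == "" | catalog$metal2 %in% metals)
  }
  if (!is.null(terminals)) {
    terminals <- vapply(terminals, .match_terminal, character(1), USE.NAMES = FALSE)
    keep <- keep & catalog$terminal %in% terminals
  }
  if (!is.null(n_range)) {
    stopifnot(length(n_range) == 2L)
    keep <- keep & catalog$n >= n_range[1] & catalog$n <= n_range[2]
  }
  if (isTRUE(nops)) keep <- keep & .nops_pass_vec(catalog$formula, nops_rule)
  cand <- catalog[keep, , drop = FALSE]

  empty <- data.frame(query_mz = numeric(), name = character(),
                      formula = character(), adduct = character(),
                      theoretical_mz = numeric(), ppm_error = numeric(),
                      terminal = character(), n = integer(),
                      disulfides = integer(), metals = character(),
                      bridge = character(), stringsAsFactors = FALSE)
  if (!nrow(cand)) return(empty)

  # theoretical m/z for every (species, adduct) pair, sorted for window search
  ns <- nrow(cand); na <- nrow(adt)
  sp_i <- rep(seq_len(ns), times = na)
  ad_i <- rep(seq_len(na), each = ns)
  theo <- (cand$monoisotopic_mass[sp_i] + adt$mass_delta[ad_i]) / adt$z[ad_i]
  ord <- order(theo)
  theo_s <- theo[ord]; sp_s <- sp_i[ord]; ad_s <- ad_i[ord]

  res <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    half <- tolerance_ppm * 1e-6  # window on theoretical: |q - t| <= half * t
    # window slightly widened; exact ppm test below decides membership
    lo <- findInterval(q / (1 + half) * (1 - 1e-12), theo_s) + 1L
    hi <- findInterval(q / (1 - half) * (1 + 1e-12), theo_s)
    if (hi < lo) next
    j <- lo:hi
    ppm <- ppm_difference(q, theo_s[j])
    inside <- abs(ppm) <= tolerance_ppm
    if (!any(inside)) next
    j <- j[inside]; ppm <- ppm[inside]
    o <- order(abs(ppm))
    j <- j[o]; ppm <- ppm[o]
    s <- sp_s[j]
    res[[qi]] <- data.frame(
      query_mz = q,
      name = cand$name[s],
      formula = cand$formula[s],
      adduct = adt$name[ad_s[j]],
      theoretical_mz = theo_s[j],
      ppm_error = ppm,
      terminal = cand$terminal[s],
      n = cand$n[s],
      disulfides = cand$disulfides[s],
      metals = ifelse(cand$metal1[s] == "", "",
               ifelse(cand$metal2[s] == "", cand$metal1[s],
                      paste0(cand$metal1[s], "+", cand$metal2[s]))),
      bridge = cand$bridge[s],
      stringsAsFactors = FALSE
    )
  }
  res <- Filter(Negate(is.null), res)
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
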