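# Independent brute-force oracle for the species catalog.
#
# Deliberately avoids the package's enumeration and formula machinery:
# formulas are plain named count vectors assembled from the printed
# n = 2 base formulas and the C8H12N2O4S repeat-unit delta, masses are
# summed directly from the shipped isotope CSV, and every (terminal, n,
# m, metal multiset, bridge) tuple is visited by explicit loops filtered
# only by the two-free-thiols-per-ion rule.

oracle_mass_lookup <- function() {
  iso <- utils::read.csv(system.file("extdata", "isotope_masses.csv",
                                     package = "pyctools"))
  stats::setNames(iso$exact_mass_da, iso$element)
}

# printed n = 2 base formulas, one per composition-distinct family
.oracle_base2 <- list(
  Gly  = c(C = 18, H = 29, N = 5, O = 10, S = 2),
  Ala  = c(C = 19, H = 31, N = 5, O = 10, S = 2),
  none = c(C = 16, H = 26, N = 4, O = 9, S = 2),
  Gln  = c(C = 21, H = 34, N = 6, O = 11, S = 2),
  Ser  = c(C = 19, H = 31, N = 5, O = 11, S = 2),
  Glu  = c(C = 21, H = 33, N = 5, O = 12, S = 2)
)
.oracle_repeat <- c(C = 8, H = 12, N = 2, O = 4, S = 1)

oracle_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out[out != 0]
}

oracle_formula_string <- function(cnt) {
  els <- names(cnt)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(cnt[ord] == 1, "", cnt[ord]), collapse = "")
}

# enumerate every admissible tuple; returns data.frame(formula, mass)
oracle_catalog <- function(terminals = names(.oracle_base2),
                           n_range = 2:11,
                           metals = c("Cd", "Co", "Cu", "Fe", "Pb", "Mn",
                                      "Hg", "Ni", "Zn", "Ag", "Se", "Ca",
                                      "Mg"),
                           include_bridges = TRUE) {
  lk <- oracle_mass_lookup()
  h_loss <- function(sym) if (sym == "Ag") 1 else 2
  bridges <- if (include_bridges) list(none = c(), sulfido = c(S = 1),
                                       disulfido = c(S = 2), selenido = c(Se = 1))
             else list(none = c())
  rows <- list(); k <- 0L
  for (term in terminals) {
    for (n in n_range) {
      base_n <- .oracle_base2[[term]]
      for (r in seq_len(n - 2)) base_n <- oracle_add(base_n, .oracle_repeat)
      for (m in 0:min(n %/% 2, 5)) {
        f0 <- oracle_add(base_n, c(H = -2 * m))
        free <- n - 2 * m
        k <- k + 1L
        rows[[k]] <- list(f = f0, nm = 0L)
        if (free >= 2) {
          for (met in metals) {
            k <- k + 1L
            rows[[k]] <- list(f = oracle_add(f0, oracle_add(
              c(H = -h_loss(met)), stats::setNames(1, met))), nm = 1L)
          }
        }
        if (free >= 4) {
          for (i in seq_along(metals)) for (j in i:length(metals)) {
            two <- oracle_add(
              oracle_add(c(H = -h_loss(metals[i]) - h_loss(metals[j])),
                         stats::setNames(1, metals[i])),
              stats::setNames(1, metals[j]))
            for (b in names(bridges)) {
              k <- k + 1L
              rows[[k]] <- list(f = oracle_add(f0, oracle_add(two, bridges[[b]])),
                                nm = 2L)
            }
          }
        }
      }
    }
  }
  data.frame(
    formula = vapply(rows, function(r) oracle_formula_string(r$f), character(1)),
    mass = vapply(rows, function(r) sum(r$f * lk[names(r$f)]), numeric(1)),
    n_metals = vapply(rows, `[[`, integer(1), "nm"),
    stringsAsFactors = FALSE
  )
}
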