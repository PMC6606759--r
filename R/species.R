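# Species construction rules
#
# A phytochelatin (PyC) is (gamma-Glu-Cys)n-X with n = 2..11 repeats and a
# C-terminal residue X in {Gly, Ala (= beta-Ala by composition), none, Gln,
# Ser, Glu}. The bare backbone of n condensed repeats is C(8n)H(12n+2)
# N(2n)O(4n+1)S(n); each terminal residue adds a fixed element delta.
# Oxidation and metal binding are pure formula arithmetic on that base:
#   - each disulfide bond removes 2 H and consumes 2 cysteine thiols;
#   - each bound divalent ion (and Se) removes 2 H, Ag(1+) removes 1 H,
#     and every bound ion consumes 2 free thiols;
#   - two-metal complexes additionally admit bridged variants adding one S
#     (sulfido), two S (disulfido) or one Se (selenido).

.TERMINALS <- c("Gly", "Ala", "none", "Gln", "Ser", "Glu")
.T_DELTA <- list(
  Gly  = c(C = 2L, H = 3L, N = 1L, O = 1L),
  Ala  = c(C = 3L, H = 5L, N = 1L, O = 1L),
  none = c(),
  Gln  = c(C = 5L, H = 8L, N = 2L, O = 2L),
  Ser  = c(C = 3L, H = 5L, N = 1L, O = 2L),
  Glu  = c(C = 5L, H = 7L, N = 1L, O = 3L)
)
.METALS <- c("Cd", "Co", "Cu", "Fe", "Pb", "Mn", "Hg", "Ni", "Zn", "Ag",
             "Se", "Ca", "Mg")
.BRIDGES <- c("none", "sulfido", "disulfido", "selenido")
.BRIDGE_DELTA <- list(none = c(), sulfido = c(S = 1L),
                      disulfido = c(S = 2L), selenido = c(Se = 1L))
.BRIDGE_SUFFIX <- c(none = "", sulfido = "(S)", disulfido = "(S2)",
                    selenido = "(Se)")

#' Terminal residue registry
#'
#' The six composition-distinct C-terminal residues of phytochelatins.
#' Ala and beta-Ala have identical elemental composition and are carried
#' as one record with an alias. \code{delta_formula} is the element delta
#' relative to the bare (no terminal residue) backbone.
#'
#' @return Data frame with columns \code{terminal}, \code{aliases},
#'   \code{delta_formula}.
#' @export
terminal_residues <- function() {
  data.frame(
    terminal = .TERMINALS,
    aliases = ifelse(.TERMINALS == "Ala", "beta-Ala", ""),
    delta_formula = vapply(.T_DELTA, function(d)
      if (length(d)) format_formula(d) else "", character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Metal registry
#'
#' The 13 bound species of the catalog: nine divalent metals (Cd, Co, Cu,
#' Fe, Pb, Mn, Hg, Ni, Zn), monovalent Ag, selenium (bound through a
#' selenotrisulfide -S-Se-S- linkage, formally divalent in the mass
#' arithmetic), and the hard acids Ca and Mg. \code{h_loss_per_ion} is the
#' number of thiol protons removed per bound ion (1 for Ag, 2 otherwise);
#' every ion consumes two cysteine thiols.
#'
#' @return Data frame with columns \code{symbol}, \code{isotope_label},
#'   \code{exact_mass_da}, \code{h_loss_per_ion},
#'   \code{thiols_required_per_ion}.
#' @export
metal_registry <- function() {
  iso <- isotope_masses()
  i <- match(.METALS, iso$element)
  data.frame(
    symbol = .METALS,
    isotope_label = iso$isotope_label[i],
    exact_mass_da = iso$exact_mass_da[i],
    h_loss_per_ion = ifelse(.METALS == "Ag", 1L, 2L),
    thiols_required_per_ion = 2L,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2 || n > 11)
    stop("repeat count n must be an integer in 2..11")
  as.integer(n)
}

#' Maximum number of disulfide bonds for a chain length
#'
#' A chain of n repeats has n cysteines, so floor(n/2) disulfides are
#' geometrically possible; the catalog caps the count at 5.
#'
#' @param n Repeat count(s), 2..11 (vectorized).
#' @return Integer vector of caps.
#' @export
max_disulfides <- function(n) pmin(n %/% 2L, 5L)

#' Number of free cysteine thiols
#'
#' A species with n repeats and m disulfide bonds retains n - 2m reduced
#' thiols; each bound metal ion requires two of them.
#'
#' @param n Repeat count(s) (vectorized).
#' @param m Disulfide count(s), m <= floor(n/2).
#' @return Integer vector n - 2m.
#' @examples
#' free_thiol_count(6, 2)
#' @export
free_thiol_count <- function(n, m) {
  if (any(m < 0) || any(m > n %/% 2L)) stop("m must satisfy 0 <= m <= floor(n/2)")
  as.integer(n - 2L * m)
}

#' Base elemental formula of an unbound, fully reduced phytochelatin
#'
#' Builds the formula of (gamma-Glu-Cys)n-terminal with all thiols reduced.
#' Each additional repeat unit adds exactly C8H12N2O4S.
#'
#' @param terminal One of `"Gly"`, `"Ala"`, `"none"`, `"Gln"`, `"Ser"`,
#'   `"Glu"` (`"beta-Ala"` is accepted as an alias of `"Ala"`).
#' @param n Repeat count, 2..11.
#' @return Named integer vector of element counts.
#' @examples
#' format_formula(base_formula("Gly", 2))  # "C18H29N5O10S2"
#' @export
base_formula <- function(terminal, n) {
  terminal <- .match_terminal(terminal)
  n <- .check_n(n)
  bb <- c(C = 8L * n, H = 12L * n + 2L, N = 2L * n, O = 4L * n + 1L, S = n)
  combine_formula(bb, .T_DELTA[[terminal]])
}

.match_terminal <- function(terminal) {
  stopifnot(is.character(terminal), length(terminal) == 1L)
  if (terminal %in% c("beta-Ala", "bAla", "b-Ala")) terminal <- "Ala"
  if (!terminal %in% .TERMINALS)
    stop(sprintf("unknown terminal residue '%s' (expected one of %s)",
                 terminal, paste(.TERMINALS, collapse = ", ")))
  terminal
}

#' Construct a single catalog species
#'
#' Applies the construction rules for one (terminal, n, m, metals, bridge)
#' tuple and returns the species with its formula, monoisotopic mass and
#' name. Preconditions enforced: m within the disulfide cap, at most two
#' bound ions, two free thiols per bound ion, bridges only on two-metal
#' species.
#'
#' @param terminal Terminal residue label.
#' @param n Repeat count, 2..11.
#' @param m Disulfide count, 0..min(floor(n/2), 5).
#' @param metals Character vector (length 0..2) of bound metal symbols.
#' @param bridge One of `"none"`, `"sulfido"`, `"disulfido"`, `"selenido"`.
#' @return An object of class `pyc_species`: a list with fields
#'   `terminal`, `n`, `m`, `metals`, `bridge`, `formula` (named integer
#'   vector), `mass` (Da) and `name`.
#' @examples
#' sp <- pyc_species("Gly", 2, m = 0, metals = "Cd")
#' sp$name
#' format_formula(sp$formula)
#' @export
pyc_species <- function(terminal, n, m = 0L, metals = character(),
                        bridge = "none") {
  terminal <- .match_terminal(terminal)
  n <- .check_n(n)
  f <- base_formula(terminal, n)
  sp <- structure(
    list(terminal = terminal, n = n, m = 0L, metals = character(),
         bridge = "none", formula = f, mass = monoisotopic_mass(f),
         name = NA_character_),
    class = "pyc_species"
  )
  if (m > 0) sp <- apply_disulfides(sp, m)
  if (length(metals)) sp <- bind_metals(sp, metals)
  if (bridge != "none") {
    bridge <- match.arg(bridge, .BRIDGES)
    sp <- .apply_bridge(sp, bridge)
  }
  sp$name <- species_name(sp)
  sp
}

#' Oxidize a species to its m-disulfide form
#'
#' Subtracts 2 H per disulfide bond from a fully reduced species.
#'
#' @param species A `pyc_species` with no disulfides yet.
#' @param m Target disulfide count, at most min(floor(n/2), 5).
#' @return The oxidized species.
#' @export
apply_disulfides <- function(species, m) {
  stopifnot(inherits(species, "pyc_species"), species$m == 0L)
  if (m < 0 || m != round(m)) stop("disulfide count must be a non-negative integer")
  if (m > max_disulfides(species$n))
    stop(sprintf("m = %d exceeds the disulfide cap min(floor(n/2), 5) = %d for n = %d",
                 m, max_disulfides(species$n), species$n))
  if (m == 0L) return(species)
  species$formula <- combine_formula(species$formula, c(H = -2L * m))
  species$m <- as.integer(m)
  species$mass <- monoisotopic_mass(species$formula)
  species$name <- species_name(species)
  species
}

#' Bind one or two metal ions to a species
#'
#' Removes the per-ion thiol protons (2 H for divalents and Se, 1 H for
#' Ag) and adds the metal atoms. Requires two free thiols per bound ion:
#' a species with n repeats and m disulfides can carry at most
#' floor((n - 2m)/2) ions.
#'
#' @param species A metal-free `pyc_species`.
#' @param metals Character vector of 1 or 2 metal symbols (order
#'   irrelevant; stored sorted).
#' @return The complexed species.
#' @examples
#' bind_metals(pyc_species("Gly", 4), c("Hg", "Hg"))$mass
#' @export
bind_metals <- function(species, metals) {
  stopifnot(inherits(species, "pyc_species"), length(species$metals) == 0L)
  reg <- metal_registry()
  if (length(metals) < 1L || length(metals) > 2L)
    stop("metals must contain 1 or 2 symbols")
  bad <- setdiff(metals, reg$symbol)
  if (length(bad))
    stop(sprintf("unknown metal symbol(s): %s", paste(bad, collapse = ", ")))
  need <- sum(reg$thiols_required_per_ion[match(metals, reg$symbol)])
  avail <- free_thiol_count(species$n, species$m)
  if (avail < need)
    stop(sprintf("insufficient free thiols: %d available, %d required for %s",
                 avail, need, paste(metals, collapse = "+")))
  h_loss <- sum(reg$h_loss_per_ion[match(metals, reg$symbol)])
  delta <- c(H = -h_loss)
  for (sym in metals) {
    delta[sym] <- if (is.na(delta[sym])) 1L else delta[sym] + 1L
  }
  species$formula <- combine_formula(species$formula, delta)
  species$metals <- sort(metals)
  species$mass <- monoisotopic_mass(species$formula)
  species$name <- species_name(species)
  species
}

.apply_bridge <- function(species, bridge) {
  species$formula <- combine_formula(species$formula, .BRIDGE_DELTA[[bridge]])
  species$bridge <- bridge
  species$mass <- monoisotopic_mass(species$formula)
  species$name <- species_name(species)
  species
}

#' Bridged variants of a two-metal complex
#'
#' For a two-metal species, returns the four catalog variants: the plain
#' complex plus the sulfido (+1 S), disulfido (+2 S) and selenido (+1 Se)
#' bridged forms, by analogy with bridging sulfurs in iron-sulfur
#' clusters. No combined S+Se or diselenido variant exists. Bridges are
#' never applied to species with fewer than two bound ions.
#'
#' @param species A two-metal `pyc_species` with `bridge == "none"`.
#' @return Named list of four `pyc_species`: `none`, `sulfido`,
#'   `disulfido`, `selenido`.
#' @export
bridge_variants <- function(species) {
  stopifnot(inherits(species, "pyc_species"))
  if (length(species$metals) != 2L)
    stop("bridged variants exist only for two-metal species")
  if (species$bridge != "none") stop("species already carries a bridge")
  out <- lapply(.BRIDGES[-1], function(b) .apply_bridge(species, b))
  c(list(none = species), stats::setNames(out, .BRIDGES[-1]))
}

#' Catalog name of a species
#'
#' Grammar: optional "(S-S)" disulfide prefix (with the count appended
#' when m > 1), "PyC" plus the repeat count, a terminal-residue suffix
#' (omitted for the bare backbone), a metal suffix ("-Cd", "-Cd(2)",
#' "-CdZn"), and a bridge suffix ("(S)", "(S2)", "(Se)").
#'
#' @param species A `pyc_species`.
#' @return A single string, e.g. `"(S-S)PyC2-Gly"` or `"PyC4-Gly-Cd(2)"`.
#' @export
species_name <- function(species) {
  stopifnot(inherits(species, "pyc_species"))
  .name_parts(species$terminal, species$n, species$m,
              c(species$metals, rep("", 2 - length(species$metals)))[1],
              c(species$metals, rep("", 2 - length(species$metals)))[2],
              species$bridge)
}

# vectorized naming shared by species_name() and enumerate_catalog()
.name_parts <- function(terminal, n, m, metal1, metal2, bridge) {
  prefix <- ifelse(m == 0L, "", ifelse(m == 1L, "(S-S)", paste0("(S-S)", m)))
  tsuf <- ifelse(terminal == "none", "", paste0("-", terminal))
  msuf <- ifelse(metal1 == "", "",
          ifelse(metal2 == "", paste0("-", metal1),
          ifelse(metal1 == metal2, paste0("-", metal1, "(2)"),
                 paste0("-", metal1, metal2))))
  bsuf <- .BRIDGE_SUFFIX[bridge]
  paste0(prefix, "PyC", n, tsuf, msuf, bsuf)
}

#' @export
print.pyc_species <- function(x, ...) {
  cat(sprintf("<pyc_species> %s\n  formula %s   monoisotopic mass %.6f Da\n",
              x$name, format_formula(x$formula), x$mass))
  if (length(x$metals))
    cat(sprintf("  bound: %s; bridge: %s\n",
                paste(x$metals, collapse = "+"), x$bridge))
  invisible(x)
}

#' Enumeration configuration
#'
#' Defaults reproduce the published catalog: all six terminal families,
#' n = 2..11, up to five disulfides, all 13 metals, up to two bound ions,
#' bridged two-metal variants included.
#'
#' @param terminals Character vector of terminal residue labels.
#' @param n_min,n_max Repeat-count range within 2..11.
#' @param metals Character vector of metal symbols to include.
#' @param max_metals Maximum bound ions per species (0, 1 or 2).
#' @param include_bridges Include sulfido/disulfido/selenido variants of
#'   two-metal complexes.
#' @param max_disulfides Cap on disulfide count (default 5).
#' @return A list of class `pyc_config`.
#' @export
enumeration_config <- function(terminals = .TERMINALS, n_min = 2L, n_max = 11L,
                               metals = .METALS, max_metals = 2L,
                               include_bridges = TRUE, max_disulfides = 5L) {
  terminals <- vapply(terminals, .match_terminal, character(1), USE.NAMES = FALSE)
  stopifnot(!anyDuplicated(terminals),
            n_min >= 2, n_max <= 11, n_min <= n_max,
            all(metals %in% .METALS), !anyDuplicated(metals),
            max_metals %in% 0:2, is.logical(include_bridges),
            max_disulfides >= 0)
  structure(list(terminals = terminals, n_min = as.integer(n_min),
                 n_max = as.integer(n_max), metals = metals,
                 max_metals = as.integer(max_metals),
                 include_bridges = isTRUE(include_bridges),
                 max_disulfides = as.integer(max_disulfides)),
            class = "pyc_config")
}

#' Enumerate the complete species catalog
#'
#' Generates every catalog species for a configuration, in deterministic
#' order (terminal family, n, m, sorted metal pair, bridge). With the
#' default configuration this yields 240 metal-free species, 2 340
#' one-metal complexes and 43 680 two-metal complexes (bridged variants
#' included): 46 260 species with pairwise distinct elemental formulas.
#'
#' @param config An [enumeration_config()]; defaults reproduce the full
#'   catalog.
#' @return A data frame of class `pyc_catalog` with columns `name`,
#'   `aliases`, `terminal`, `n`, `disulfides`, `metal1`, `metal2`,
#'   `bridge`, `formula`, `monoisotopic_mass`.
#' @examples
#' cat2 <- enumerate_catalog(enumeration_config(terminals = "Gly",
#'                                              n_max = 2, max_metals = 0))
#' cat2$name
#' @export
enumerate_catalog <- function(config = enumeration_config()) {
  stopifnot(inherits(config, "pyc_config"))
  els <- .known_elements()
  mass_vec <- .mass_lookup()[els]
  reg <- metal_registry()

  # scaffolds: (terminal, n, m) with m under the cap
  grid <- expand.grid(ti = seq_along(config$terminals),
                      n = config$n_min:config$n_max,
                      m = 0:min(5L, config$max_disulfides),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$m <= pmin(grid$n %/% 2L, config$max_disulfides), , drop = FALSE]

  scaffold_counts <- function(g) {
    mat <- matrix(0L, nrow(g), length(els), dimnames = list(NULL, els))
    mat[, "C"] <- 8L * g$n
    mat[, "H"] <- 12L * g$n + 2L - 2L * g$m
    mat[, "N"] <- 2L * g$n
    mat[, "O"] <- 4L * g$n + 1L
    mat[, "S"] <- g$n
    for (i in seq_along(config$terminals)) {
      d <- .T_DELTA[[config$terminals[i]]]
      if (!length(d)) next
      rows <- g$ti == i
      for (e in names(d)) mat[rows, e] <- mat[rows, e] + d[[e]]
    }
    mat
  }

  blocks <- list()

  # metal-free block
  blocks[[1]] <- list(g = grid, counts = scaffold_counts(grid),
                      metal1 = rep("", nrow(grid)), metal2 = rep("", nrow(grid)),
                      bridge = rep("none", nrow(grid)))

  h_loss <- stats::setNames(reg$h_loss_per_ion, reg$symbol)

  if (config$max_metals >= 1L && length(config$metals)) {
    g1 <- grid[grid$n - 2L * grid$m >= 2L, , drop = FALSE]
    if (nrow(g1)) {
      idx <- rep(seq_len(nrow(g1)), times = length(config$metals))
      met <- rep(config$metals, each = nrow(g1))
      cnt <- scaffold_counts(g1)[idx, , drop = FALSE]
      cnt[, "H"] <- cnt[, "H"] - h_loss[met]
      cnt[cbind(seq_along(met), match(met, els))] <-
        cnt[cbind(seq_along(met), match(met, els))] + 1L
      blocks[[2]] <- list(g = g1[idx, , drop = FALSE], counts = cnt,
                          metal1 = met, metal2 = rep("", length(met)),
                          bridge = rep("none", length(met)))
    }
  }

  if (config$max_metals >= 2L && length(config$metals)) {
    g2 <- grid[grid$n - 2L * grid$m >= 4L, , drop = FALSE]
    if (nrow(g2)) {
      ms <- sort(config$metals)
      pairs <- expand.grid(a = seq_along(ms), b = seq_along(ms),
                           KEEP.OUT.ATTRS = FALSE)
      pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]  # unordered, with repetition
      bridges <- if (config$include_bridges) .BRIDGES else "none"
      nsc <- nrow(g2); npr <- nrow(pairs); nbr <- length(bridges)
      # layout: scaffold varies slowest, then pair, then bridge
      sc_i <- rep(seq_len(nsc), each = npr * nbr)
      pr_i <- rep(rep(seq_len(npr), each = nbr), times = nsc)
      br_i <- rep(seq_len(nbr), times = nsc * npr)
      m1 <- ms[pairs$a[pr_i]]; m2 <- ms[pairs$b[pr_i]]
      cnt <- scaffold_counts(g2)[sc_i, , drop = FALSE]
      cnt[, "H"] <- cnt[, "H"] - h_loss[m1] - h_loss[m2]
      k <- seq_along(sc_i)
      cnt[cbind(k, match(m1, els))] <- cnt[cbind(k, match(m1, els))] + 1L
      cnt[cbind(k, match(m2, els))] <- cnt[cbind(k, match(m2, els))] + 1L
      br <- bridges[br_i]
      cnt[br == "sulfido", "S"] <- cnt[br == "sulfido", "S"] + 1L
      cnt[br == "disulfido", "S"] <- cnt[br == "disulfido", "S"] + 2L
      cnt[br == "selenido", "Se"] <- cnt[br == "selenido", "Se"] + 1L
      blocks[[3]] <- list(g = g2[sc_i, , drop = FALSE], counts = cnt,
                          metal1 = m1, metal2 = m2, bridge = br)
    }
  }

  blocks <- Filter(Negate(is.null), blocks)
  g <- do.call(rbind, lapply(blocks, `[[`, "g"))
  counts <- do.call(rbind, lapply(blocks, `[[`, "counts"))
  metal1 <- unlist(lapply(blocks, `[[`, "metal1"), use.names = FALSE)
  metal2 <- unlist(lapply(blocks, `[[`, "metal2"), use.names = FALSE)
  bridge <- unlist(lapply(blocks, `[[`, "bridge"), use.names = FALSE)

  if (!nrow(g)) {
    out <- data.frame(name = character(), aliases = character(),
                      terminal = character(), n = integer(),
                      disulfides = integer(), metal1 = character(),
                      metal2 = character(), bridge = character(),
                      formula = character(), monoisotopic_mass = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("pyc_catalog", "data.frame")
    attr(out, "config") <- config
    return(out)
  }

  terminal <- config$terminals[g$ti]
  name <- .name_parts(terminal, g$n, g$m, metal1, metal2, bridge)
  aliases <- ifelse(terminal == "Ala", sub("-Ala", "-betaAla", name, fixed = TRUE), "")
  formula <- .format_counts_matrix(counts)
  mass <- as.numeric(counts %*% mass_vec)

  out <- data.frame(name = name, aliases = aliases, terminal = terminal,
                    n = g$n, disulfides = g$m, metal1 = metal1,
                    metal2 = metal2, bridge = bridge, formula = formula,
                    monoisotopic_mass = mass,
                    row.names = NULL, stringsAsFactors = FALSE)
  ord <- order(match(out$terminal, config$terminals), out$n, out$disulfides,
               out$metal1, out$metal2, match(out$bridge, .BRIDGES),
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pyc_catalog", "data.frame")
  attr(out, "config") <- config
  out
}

# Hill-order formula strings for an element-count matrix whose columns are
# the known elements (C and H first by construction of .known_elements()
# via the isotope table ordering; enforce explicitly here)
.format_counts_matrix <- function(counts) {
  els <- colnames(counts)
  hill <- c("C", "H", sort(setdiff(els, c("C", "H"))))
  parts <- lapply(hill, function(e) {
    v <- counts[, e]
    ifelse(v == 0L, "", paste0(e, ifelse(v == 1L, "", v)))
  })
  do.call(paste0, parts)
}

#' @export
print.pyc_catalog <- function(x, ...) {
  cat(sprintf("<pyc_catalog> %d species (%d metal-free, %d one-metal, %d two-metal)\n",
              nrow(x), sum(x$metal1 == ""),
              sum(x$metal1 != "" & x$metal2 == ""), sum(x$metal2 != "")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
summary.pyc_catalog <- function(object, ...) {
  out <- list(
    n_species = nrow(object),
    n_metal_free = sum(object$metal1 == ""),
    n_one_metal = sum(object$metal1 != "" & object$metal2 == ""),
    n_two_metal = sum(object$metal2 != ""),
    n_unique_formulas = length(unique(object$formula)),
    mass_range = range(object$monoisotopic_mass)
  )
  class(out) <- "summary.pyc_catalog"
  out
}

#' @export
print.summary.pyc_catalog <- function(x, ...) {
  cat(sprintf(paste0("Catalog: %d species | metal-free %d | one-metal %d | ",
                     "two-metal %d\nUnique formulas: %d\nMass range: %.4f - %.4f Da\n"),
              x$n_species, x$n_metal_free, x$n_one_metal, x$n_two_metal,
              x$n_unique_formulas, x$mass_range[1], x$mass_range[2]))
  invisible(x)
}
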