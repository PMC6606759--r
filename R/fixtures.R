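# Regression fixtures and a seeded synthetic query generator, so the
# annotation workflow is testable end-to-end without any external data.

#' Reference predicted \[M+H\] m/z values
#'
#' A curated set of 35 phytochelatin and phytochelatin-metal complex
#' species whose \[M+H\] m/z values have been reported alongside
#' experimental observations (chemical standards and literature data):
#' the Gly/Ser/Gln/Glu families, one- and two-metal Hg, Cd, Pb, Zn and Mn
#' complexes and the single-disulfide PyC2-Gly form. Expected values
#' carry their reported number of decimal places (4, 3 or 2); the
#' pipeline must reproduce each after rounding to that precision.
#'
#' The label column keeps the names as reported; note the species
#' reported as "PyC4-Gly-Hg" corresponds to the single-disulfide complex
#' ((S-S)PyC4-Gly-Hg in this package's grammar), which its stored
#' construction parameters reflect.
#'
#' @return Data frame with columns `label`, `terminal`, `n`,
#'   `disulfides`, `metal1`, `metal2`, `adduct`, `expected_mz`,
#'   `decimals`.
#' @export
reference_masses <- function() {
  path <- system.file("extdata", "reference_predicted_mz.csv",
                      package = "pyctools")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(metal1 = "character",
                                       metal2 = "character"))
  df$metal1[is.na(df$metal1)] <- ""
  df$metal2[is.na(df$metal2)] <- ""
  df
}

#' Predicted adduct m/z for a reference-fixture row
#'
#' Runs the full pipeline (base formula, disulfide and metal-binding
#' rules, monoisotopic mass, adduct m/z) for one row of
#' [reference_masses()].
#'
#' @param row A one-row data frame with `terminal`, `n`, `disulfides`,
#'   `metal1`, `metal2`, `adduct`.
#' @return Predicted m/z at full precision.
#' @export
predict_reference_mz <- function(row) {
  metals <- c(row$metal1, row$metal2)
  metals <- metals[nzchar(metals)]
  sp <- pyc_species(row$terminal, row$n, m = row$disulfides, metals = metals)
  adduct_mz(sp$mass, row$adduct)
}

#' Generate a seeded synthetic query set
#'
#' Emulates an LC-MS feature mass list with known ground truth: samples
#' `n_true` catalog species uniformly, computes their adduct m/z and
#' perturbs each multiplicatively by Gaussian ppm jitter (the standard
#' instrument error model); adds `n_decoys` masses drawn uniformly over
#' the catalog's m/z range but excluded from a guard window of
#' +/- (3 * jitter + guard) ppm around every theoretical m/z, so that a
#' search at a guard-consistent tolerance can never match them.
#'
#' @param catalog A `pyc_catalog`.
#' @param n_true Number of true (annotated) queries; at most the number
#'   of (species, adduct) combinations.
#' @param n_decoys Number of decoy queries.
#' @param jitter_ppm_sd Gaussian jitter standard deviation in ppm (>= 0).
#' @param adducts Adduct names used for the true queries.
#' @param guard_ppm Extra guard margin (ppm) beyond 3 * jitter for decoy
#'   placement; defaults to 5 (a typical search tolerance).
#' @param seed Integer seed; regeneration with the same seed is
#'   identical.
#' @return A list of class `pyc_query_set`: `queries` (numeric, trues
#'   then decoys), `truth` (data frame `query_mz`, `name`, `adduct` for
#'   the true queries) and `parameters`.
#' @export
generate_query_set <- function(catalog, n_true = 100L, n_decoys = 20L,
                               jitter_ppm_sd = 1, adducts = "M+H",
                               guard_ppm = 5, seed = 1L) {
  stopifnot(inherits(catalog, "data.frame"), nrow(catalog) >= 1L,
            n_true >= 0L, n_decoys >= 0L, jitter_ppm_sd >= 0, guard_ppm > 0)
  adt <- .resolve_adducts(adducts)
  ns <- nrow(catalog); na <- nrow(adt)
  if (n_true > ns * na) stop("n_true exceeds the number of (species, adduct) combinations")
  theo_all <- as.vector(outer(catalog$monoisotopic_mass, seq_len(na),
                              function(m, j) (m + adt$mass_delta[j]) / adt$z[j]))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pick <- sample.int(ns * na, n_true)
  sp_i <- (pick - 1L) %% ns + 1L
  ad_i <- (pick - 1L) %/% ns + 1L
  theo <- theo_all[pick]
  trues <- theo * (1 + stats::rnorm(n_true, 0, jitter_ppm_sd) * 1e-6)

  decoys <- numeric(0)
  if (n_decoys > 0L) {
    rng <- range(theo_all)
    half <- (3 * jitter_ppm_sd + guard_ppm) * 1e-6
    theo_s <- sort(theo_all)
    guarded <- function(x) {
      i <- findInterval(x, theo_s)
      lo_ok <- i == 0L | x > theo_s[pmax(i, 1L)] * (1 + half)
      hi_ok <- i == length(theo_s) | x < theo_s[pmin(i + 1L, length(theo_s))] * (1 - half)
      lo_ok & hi_ok
    }
    attempts <- 0L
    while (length(decoys) < n_decoys) {
      cand <- stats::runif(n_decoys * 4L, rng[1], rng[2])
      cand <- cand[guarded(cand)]
      decoys <- c(decoys, cand)[seq_len(min(n_decoys, length(decoys) + length(cand)))]
      attempts <- attempts + 1L
      if (attempts > 100L)
        stop("cannot place decoys: catalog too dense for the requested guard window")
    }
  }

  structure(list(
    queries = c(trues, decoys),
    truth = data.frame(query_mz = trues, name = catalog$name[sp_i],
                       adduct = adt$name[ad_i], theoretical_mz = theo,
                       stringsAsFactors = FALSE),
    parameters = list(n_true = as.integer(n_true),
                      n_decoys = as.integer(n_decoys),
                      jitter_ppm_sd = jitter_ppm_sd, guard_ppm = guard_ppm,
                      adducts = adt$name, seed = as.integer(seed))
  ), class = "pyc_query_set")
}

#' Score annotation results against a synthetic query set's ground truth
#'
#' @param query_set A [generate_query_set()] result.
#' @param matches Output of [annotate_masses()] run on
#'   `query_set$queries`.
#' @return List with `recall` (fraction of true queries whose truth
#'   species name appears among their matches) and
#'   `false_annotation_count` (number of matches reported for decoy
#'   queries).
#' @export
evaluate_annotation <- function(query_set, matches) {
  stopifnot(inherits(query_set, "pyc_query_set"), is.data.frame(matches))
  truth <- query_set$truth
  if (!nrow(truth)) {
    recall <- NA_real_
  } else {
    hit <- vapply(seq_len(nrow(truth)), function(i) {
      any(matches$query_mz == truth$query_mz[i] & matches$name == truth$name[i])
    }, logical(1))
    recall <- mean(hit)
  }
  decoys <- setdiff(query_set$queries, truth$query_mz)
  list(recall = recall,
       false_annotation_count = sum(matches$query_mz %in% decoys))
}
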