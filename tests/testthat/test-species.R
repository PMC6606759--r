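test_that("base formulas reproduce the printed family formulas", {
  expect_equal(format_formula(base_formula("Gly", 2)), "C18H29N5O10S2")
  expect_equal(format_formula(base_formula("none", 2)), "C16H26N4O9S2")
  expect_equal(format_formula(base_formula("Ala", 2)), "C19H31N5O10S2")
  expect_equal(format_formula(base_formula("beta-Ala", 2)), "C19H31N5O10S2")
  expect_equal(format_formula(base_formula("Gln", 2)), "C21H34N6O11S2")
  expect_equal(format_formula(base_formula("Ser", 2)), "C19H31N5O11S2")
  expect_equal(format_formula(base_formula("Glu", 2)), "C21H33N5O12S2")
  # each repeat adds exactly C8H12N2O4S
  expect_equal(format_formula(base_formula("Gly", 3)), "C26H41N7O14S3")
  expect_equal(base_formula("Gly", 11),
               combine_formula(base_formula("Gly", 10),
                               c(C = 8L, H = 12L, N = 2L, O = 4L, S = 1L)))
  expect_error(base_formula("Gly", 1), "2..11")
  expect_error(base_formula("Gly", 12), "2..11")
  expect_error(base_formula("Trp", 2), "terminal")
})

test_that("disulfide oxidation subtracts 2H per bond under the length cap", {
  sp <- pyc_species("Gly", 2)
  ox <- apply_disulfides(sp, 1)
  expect_equal(format_formula(ox$formula), "C18H27N5O10S2")
  expect_equal(ox$name, "(S-S)PyC2-Gly")
  expect_identical(apply_disulfides(sp, 0), sp)
  expect_error(apply_disulfides(pyc_species("Gly", 3), 2), "cap")
  # cap is min(floor(n/2), 5): n = 11 still allows only 5
  expect_equal(max_disulfides(c(2, 3, 10, 11)), c(1L, 1L, 5L, 5L))
  expect_silent(pyc_species("Gly", 11, m = 5))
  expect_error(pyc_species("Gly", 11, m = 6), "cap")
})

test_that("free thiol accounting follows n - 2m", {
  expect_equal(free_thiol_count(2, 0), 2L)
  expect_equal(free_thiol_count(6, 2), 2L)
  expect_equal(free_thiol_count(4, 2), 0L)
  expect_error(free_thiol_count(4, 3), "floor")
})

test_that("metal binding applies per-ion H loss and the thiol rule", {
  cd <- bind_metals(pyc_species("Gly", 2), "Cd")
  expect_equal(format_formula(cd$formula), "C18H27CdN5O10S2")
  expect_equal(round(adduct_mz(cd$mass, "M+H"), 4), 652.0306)
  hg2 <- bind_metals(pyc_species("Gly", 4), c("Hg", "Hg"))
  expect_equal(round(adduct_mz(hg2$mass, "M+H"), 4), 1404.1564)
  # Ag(1+) removes one H per ion instead of two
  ag <- bind_metals(pyc_species("Gly", 2), "Ag")
  expect_equal(format_formula(ag$formula), "C18H28AgN5O10S2")
  # two free thiols required per bound ion, uniformly
  expect_error(bind_metals(pyc_species("Gly", 2, m = 1), "Zn"), "thiols")
  expect_error(bind_metals(pyc_species("Gly", 2), c("Ag", "Ag")), "thiols")
  expect_error(bind_metals(pyc_species("Gly", 4, m = 1), c("Cd", "Zn")), "thiols")
  expect_error(bind_metals(pyc_species("Gly", 4), "Uup"), "unknown metal")
})

test_that("two-metal complexes have exactly four bridge variants", {
  v <- bridge_variants(bind_metals(pyc_species("Gly", 4), c("Cd", "Cd")))
  expect_named(v, c("none", "sulfido", "disulfido", "selenido"))
  base <- v$none$formula
  expect_equal(v$sulfido$formula, combine_formula(base, c(S = 1L)))
  expect_equal(v$disulfido$formula, combine_formula(base, c(S = 2L)))
  expect_equal(v$selenido$formula, combine_formula(base, c(Se = 1L)))
  expect_error(bridge_variants(bind_metals(pyc_species("Gly", 2), "Cd")),
               "two-metal")
  expect_error(bridge_variants(pyc_species("Gly", 2)), "two-metal")
})

test_that("species names follow the catalog grammar", {
  expect_equal(pyc_species("Gly", 2, m = 1)$name, "(S-S)PyC2-Gly")
  expect_equal(pyc_species("Gly", 4, metals = c("Cd", "Cd"))$name,
               "PyC4-Gly-Cd(2)")
  expect_equal(pyc_species("none", 2)$name, "PyC2")
  expect_equal(pyc_species("Gly", 8, m = 2)$name, "(S-S)2PyC8-Gly")
  expect_equal(pyc_species("Ser", 4, metals = c("Zn", "Cd"))$name,
               "PyC4-Ser-CdZn")
  expect_equal(pyc_species("Glu", 4, metals = c("Hg", "Hg"),
                           bridge = "selenido")$name, "PyC4-Glu-Hg(2)(Se)")
})

test_that("restricted enumerations match the closed-form counts", {
  # brute-force over m for one family at n = 2: base + single disulfide
  tiny <- enumerate_catalog(enumeration_config(terminals = "Gly", n_max = 2,
                                               max_metals = 0))
  expect_equal(tiny$name, c("PyC2-Gly", "(S-S)PyC2-Gly"))

  # metal-free scaffolds per family: sum over n of (min(floor(n/2),5)+1) = 40
  for (k_metals in list("Cd", c("Cd", "Zn"), c("Cd", "Zn", "Ag", "Se"))) {
    k <- length(k_metals)
    cfg <- enumeration_config(metals = k_metals)
    ctl <- enumerate_catalog(cfg)
    expect_equal(sum(ctl$metal1 == ""), 6 * 40)
    expect_equal(sum(ctl$metal1 != "" & ctl$metal2 == ""), 6 * 30 * k)
    expect_equal(sum(ctl$metal2 != ""), 6 * 20 * (k * (k + 1) / 2) * 4)
    expect_false(anyDuplicated(ctl$formula) > 0)
  }
})

test_that("enumeration agrees with the independent brute-force oracle", {
  terminals <- c("Gly", "none")
  metals <- c("Cd", "Ag", "Se")
  got <- enumerate_catalog(enumeration_config(terminals = terminals,
                                              n_min = 2, n_max = 6,
                                              metals = metals))
  want <- oracle_catalog(terminals = terminals, n_range = 2:6, metals = metals)
  expect_equal(nrow(got), nrow(want))
  expect_equal(sort(got$formula), sort(want$formula))
  # masses agree species-by-species (formulas are unique keys in both)
  expect_equal(got$monoisotopic_mass[order(got$formula)],
               want$mass[order(want$formula)], tolerance = 1e-9)
  # stratum counts agree too
  for (nm in 0:2) {
    expect_equal(sum((got$metal1 != "") + (got$metal2 != "") == nm),
                 sum(want$n_metals == nm))
  }
})

test_that("catalog ordering is deterministic and aliases mark Ala forms", {
  a <- enumerate_catalog(enumeration_config(terminals = c("Ala", "Gly"),
                                            n_max = 4, metals = "Zn"))
  b <- enumerate_catalog(enumeration_config(terminals = c("Ala", "Gly"),
                                            n_max = 4, metals = "Zn"))
  expect_identical(a, b)
  ala <- a[a$terminal == "Ala", ]
  expect_true(all(grepl("betaAla", ala$aliases)))
  expect_true(all(a$aliases[a$terminal != "Ala"] == ""))
})
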