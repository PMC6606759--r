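test_that("adduct m/z follows (M + delta)/z with the proton convention", {
  expect_equal(sprintf("%.4f", adduct_mz(539.13558415, "M+H")), "540.1429")
  expect_equal(sprintf("%.4f", adduct_mz(1003.23913989, "M+H")), "1004.2464")
  # identity adduct: zero delta, unit charge
  ident <- data.frame(name = "M", mass_delta = 0, z = 1L)
  expect_equal(adduct_mz(500.5, ident), 500.5)
  # doubly protonated: (M + 2p)/2
  expect_equal(adduct_mz(1000, "M+2H"), (1000 + 2 * proton_mass) / 2)
  expect_error(adduct_mz(500, "M+X"), "unknown adduct")
  expect_error(adduct_mz(-1, "M+H"))
})

test_that("ppm error is signed, theoretical-denominated and near-symmetric", {
  expect_equal(round(ppm_difference(538.1254, 538.1272), 1), -3.3)
  expect_equal(round(ppm_difference(540.1437, 540.1429), 1), 1.5)
  expect_equal(ppm_difference(777.7, 777.7), 0)
  # swapping arguments changes |ppm| only at relative order ppm * 1e-6
  set.seed(11)
  for (i in 1:20) {
    t <- runif(1, 100, 2000)
    o <- t * (1 + runif(1, -1e-5, 1e-5))
    d <- abs(abs(ppm_difference(o, t)) - abs(ppm_difference(t, o)))
    expect_lt(d, abs(ppm_difference(o, t)) * 2e-5 + 1e-9)
  }
})

test_that("NOPS ratio check passes catalog chemistry and fails closed", {
  expect_true(nops_check("C18H29N5O10S2"))
  expect_false(nops_check("C1N5O10S2"))
  expect_false(nops_check(c(H = 2L, O = 1L)))  # carbon-free
  # thresholds act element-wise
  expect_false(nops_check("C10S9"))              # S/C = 0.9 > 0.8
  expect_true(nops_check("C10S8"))
  expect_true(nops_check("C10N13"))              # N/C = 1.3 boundary
  expect_false(nops_check("C10N13", nops_rule(n_c = 1.2)))
  # metals never enter a ratio
  expect_true(nops_check("C18H27CdN5O10S2"))
})

test_that("annotation recovers the disulfide worked example", {
  cat_gly <- enumerate_catalog(enumeration_config(terminals = "Gly"))
  m <- annotate_masses(538.1270, cat_gly, adducts = "M+H", tolerance_ppm = 5)
  expect_true("(S-S)PyC2-Gly" %in% m$name)
  row <- m[m$name == "(S-S)PyC2-Gly", ]
  expect_equal(row$formula, "C18H27N5O10S2")
  expect_lte(abs(row$ppm_error), 5)
  # shrinking the tolerance kills the match
  expect_equal(nrow(annotate_masses(538.1270, cat_gly, adducts = "M+H",
                                    tolerance_ppm = 0.01)), 0L)
})

test_that("every species round-trips through its own adduct m/z", {
  ctl <- enumerate_catalog(enumeration_config(terminals = c("Gly", "Gln"),
                                              metals = c("Cd", "Hg", "Se")))
  set.seed(3)
  idx <- sample(nrow(ctl), 40)
  for (ad in c("M+H", "M+2H")) {
    q <- adduct_mz(ctl$monoisotopic_mass[idx], ad)
    m <- annotate_masses(q, ctl, adducts = ad, tolerance_ppm = 0.5)
    hit <- vapply(seq_along(idx), function(i)
      any(m$query_mz == q[i] & m$name == ctl$name[idx[i]]), logical(1))
    expect_true(all(hit))
  }
})

test_that("match sets are monotone in tolerance", {
  ctl <- enumerate_catalog(enumeration_config(terminals = "Ser",
                                              metals = c("Zn", "Cd")))
  set.seed(5)
  q <- sample(ctl$monoisotopic_mass, 30) + proton_mass
  q <- q * (1 + rnorm(30, 0, 3) * 1e-6)
  prev <- NULL
  for (tol in c(0.5, 1, 2, 5, 10)) {
    m <- annotate_masses(q, ctl, adducts = "M+H", tolerance_ppm = tol)
    key <- paste(m$query_mz, m$name, m$adduct)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("species filters restrict the candidate set as documented", {
  ctl <- enumerate_catalog(enumeration_config(terminals = c("Gly", "Ser"),
                                              metals = c("Zn", "Cd")))
  q <- adduct_mz(ctl$monoisotopic_mass, "M+H")[seq(1, nrow(ctl), by = 7)]
  m <- annotate_masses(q, ctl, tolerance_ppm = 5, metals = "Zn")
  expect_true(nrow(m) > 0)
  expect_true(all(grepl("Zn", m$metals)))
  m2 <- annotate_masses(q, ctl, tolerance_ppm = 5, terminals = "Ser",
                        n_range = c(2, 4))
  expect_true(all(m2$terminal == "Ser"))
  expect_true(all(m2$n >= 2 & m2$n <= 4))
  # NOPS filtering never widens a match set
  m3 <- annotate_masses(q, ctl, tolerance_ppm = 5)
  m4 <- annotate_masses(q, ctl, tolerance_ppm = 5, nops = TRUE)
  expect_lte(nrow(m4), nrow(m3))
})

test_that("annotation rejects degenerate inputs", {
  ctl <- enumerate_catalog(enumeration_config(terminals = "Gly", n_max = 3,
                                              max_metals = 0))
  expect_error(annotate_masses(numeric(0), ctl), "non-empty")
  expect_error(annotate_masses(c(540.1, NA), ctl), "missing")
  expect_error(annotate_masses(540.1, ctl, adducts = character(0)), "non-empty")
  expect_error(annotate_masses(540.1, ctl, tolerance_ppm = 0))
})
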