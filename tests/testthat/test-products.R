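test_that("formula arithmetic is element-wise and guarded", {
  a <- chem_formula(C = 8, H = 16, N = 2, O = 2, S = 1)
  b <- chem_formula(H = 1)
  expect_equal(format(formula_subtract(a, b)), "C8H15N2O2S")
  expect_equal(format(formula_add(b, formula_subtract(a, b))), "C8H16N2O2S")
  expect_error(formula_subtract(b, a), "negative")
  expect_error(chem_formula(Xx = 1), "unknown element")
  expect_equal(monoisotopic_mass(chem_formula()), 0)
})

test_that("monoisotopic masses agree with the independent oracle", {
  expect_equal(monoisotopic_mass(parent_formula(1)), ORACLE_MASS$parent1,
               tolerance = 1e-6)
  expect_equal(monoisotopic_mass(parent_formula(2)), ORACLE_MASS$parent2,
               tolerance = 1e-6)
})

test_that("dimer MH+ reproduces the measured accurate masses", {
  expect_equal(dimer_mh("aS2", "aS2", 1), 407.1781, tolerance = 5e-4 / 407)
  expect_equal(dimer_mh("aS2", "aS2", 2), 379.1468, tolerance = 5e-4 / 379)
  expect_equal(dimer_mh("aS1", "aC1", 1), dimer_mh("aC1", "aS1", 1))
  expect_equal(dimer_mh("aS1", "aS2", 1), ORACLE_MASS$dimer1_mh,
               tolerance = 1e-6)
  expect_error(dimer_mh("aC1", "aC1", 2), "unknown radical")
})

test_that("CH3S adduct masses match the oracle", {
  expect_equal(adduct_mh("aS1", 1), ORACLE_MASS$adduct1_mh, tolerance = 1e-6)
  expect_equal(adduct_mh("aC2", 2), ORACLE_MASS$adduct2_mh, tolerance = 1e-6)
  # isomeric halves share a formula: adduct - dimer difference is constant
  d1 <- vapply(c("aS1", "aS2", "aC1", "aC2"),
               function(r) adduct_mh(r, 1) - dimer_mh(r, r, 1), numeric(1))
  expect_equal(max(d1) - min(d1), 0)
})

test_that("all dimers of one compound are isobaric", {
  for (cp in 1:2) {
    tab <- enumerate_products(cp, include_adducts = FALSE)
    expect_equal(max(tab$mh) - min(tab$mh), 0)
  }
})

test_that("product enumeration has the combinatorial counts", {
  t1 <- enumerate_products(1)
  expect_equal(sum(t1$type == "dimer"), 10)  # C(4,2) + 4 homodimers
  expect_equal(sum(t1$type == "adduct"), 4)
  t2 <- enumerate_products(2)
  expect_equal(sum(t2$type == "dimer"), 6)
  expect_equal(sum(t2$type == "adduct"), 3)
  single <- enumerate_products(1, radicals = "aS2", include_adducts = FALSE)
  expect_equal(nrow(single), 1)
  expect_true(single$homodimer)
  expect_error(enumerate_products(1, radicals = character()), "empty")
})

test_that("diastereoisomer counts reproduce the reported stereochemistry", {
  expect_equal(count_diastereomers("aS2", "aS2", 1), 3)  # SSSS, SRSS, SRRS
  expect_equal(count_diastereomers("aS2", "aC1", 1), 4)
  expect_equal(count_diastereomers("aS2", "aS1", 1), 2)  # SSS, SRS
  expect_equal(count_diastereomers("aS2", "aC2", 1), 2)
  # the three aS1-containing products total four diastereoisomers
  aS1_set <- c(count_diastereomers("aS1", "aS1", 1),
               count_diastereomers("aS1", "aC1", 1),
               count_diastereomers("aS1", "aC2", 1))
  expect_equal(aS1_set, c(1, 2, 1))
  expect_equal(sum(aS1_set), 4)
  # no fixed centre: merging enantiomers collapses the mirror pair
  expect_equal(count_diastereomers("aC1", "aC1", 1, merge_enantiomers = TRUE),
               2)
  expect_equal(count_diastereomers("aC1", "aC1", 1,
                                   merge_enantiomers = FALSE), 3)
})

test_that("counts equal the brute-force enumeration oracle on every pair", {
  for (cp in 1:2) {
    reg <- radical_registry(cp, include_ch3s = TRUE)
    for (pair in all_pair_types(cp)) {
      a <- reg[match(pair[1], reg$name), ]
      b <- reg[match(pair[2], reg$name), ]
      for (merge in c(TRUE, FALSE)) {
        expect_equal(
          count_diastereomers(pair[1], pair[2], cp, merge_enantiomers = merge),
          oracle_diastereomers(a$fixed_centers, a$gains_center,
                               b$fixed_centers, b$gains_center,
                               homodimer = pair[1] == pair[2],
                               merge_enantiomers = merge),
          info = paste(cp, pair[1], pair[2], merge))
      }
    }
  }
})

test_that("homodimer and heterodimer counts are argument-order invariant", {
  for (pair in all_pair_types(1)) {
    expect_equal(count_diastereomers(pair[1], pair[2], 1),
                 count_diastereomers(pair[2], pair[1], 1))
  }
})

test_that("footprint normalisation reproduces the reported ratios", {
  r1 <- normalize_footprint(c(aS2 = 154, aS1 = 94, aC1 = 14, aC2 = 10))
  expect_equal(unname(r1), c(15.4, 9.4, 1.4, 1.0))
  # scale invariance
  base <- c(aS2 = 72.2, aS1 = 1.0, aC2 = 2.3)
  for (c0 in c(0.37, 1, 250)) {
    expect_equal(normalize_footprint(base * c0), base)
  }
  expect_equal(unname(normalize_footprint(c(x = 5))), 1)
  expect_error(normalize_footprint(c(a = 1, b = 0)), "positive")
})

test_that("peak matching annotates isobaric dimers as ambiguous", {
  prods <- enumerate_products(1)
  peaks <- data.frame(mz = c(407.1781, 1000), intensity = c(100, 5))
  res <- match_peaks(peaks, prods, tol_ppm = 5)
  expect_equal(res$n_matches[1], 10)  # every dimer is isobaric
  expect_true(res$ambiguous[1])
  expect_equal(res$n_matches[2], 0)
  # degenerate tolerance: only exact float equality
  exact <- match_peaks(data.frame(mz = prods$mh[1], intensity = 1), prods,
                       tol_ppm = 0)
  expect_gte(exact$n_matches[1], 1)
  off <- match_peaks(data.frame(mz = prods$mh[1] + 1e-9, intensity = 1),
                     prods, tol_ppm = 0)
  expect_equal(off$n_matches[1], 0)
})
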