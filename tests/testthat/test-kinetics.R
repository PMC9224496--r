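test_that("default schemes carry the printed rate constants and topology", {
  s1 <- scheme_compound1()
  ks <- vapply(s1$reactions, `[[`, numeric(1), "k")
  labs <- vapply(s1$reactions, `[[`, character(1), "label")
  expect_true(any(ks == 5.6e5 & grepl("HOS decay", labs)))
  expect_true("SN" %in% s1$species)
  expect_false("SO" %in% s1$species)

  s2 <- scheme_compound2()
  expect_true("SO" %in% s2$species)
  expect_false("SN" %in% s2$species)
  expect_false("aC1" %in% s2$species)
  expect_gte(s2$params$k_so, 6e7)

  sh <- scheme_h_atom(1)
  expect_true(any(vapply(sh$reactions, `[[`, numeric(1), "k") == 1.7e9))
  # one CH3S adduct sink per carbon radical of the compound
  expect_setequal(grep("^Add_", sh$species, value = TRUE),
                  c("Add_aS", "Add_aC1", "Add_aC2"))
  expect_setequal(grep("^Add_", scheme_h_atom(2)$species, value = TRUE),
                  c("Add_aS", "Add_aC2"))
})

test_that("pure addition branching forms no abstraction radicals early", {
  s <- scheme_compound1(list(f_hos = 1, f_ac1 = 0, f_as = 0, f_ac2 = 0,
                             k_d = 0, k_rr = 0))
  tr <- simulate_scheme(s, seq(1e-8, 2e-6, length.out = 20))
  expect_true(all(tr$conc[, c("aS", "aC1", "aC2")] < 1e-15))
  expect_gt(max(tr$conc[, "HOS"]), 0)
})

test_that("zero initial radicals give an all-zero trace", {
  s <- scheme_compound1(list(g_ho = 0))
  s$initial["HO"] <- 0
  tr <- simulate_scheme(s, seq(1e-7, 1e-4, length.out = 10))
  expect_true(all(abs(tr$conc[, setdiff(s$species, "M")]) < 1e-18))
})

test_that("an isolated first-order decay matches the exponential", {
  k <- 5.6e5
  s <- reaction_scheme(c("A", "B"), list(reaction("A", "B", k)),
                       initial = c(A = 1e-6))
  t <- seq(0, 1e-5, length.out = 40)
  tr <- simulate_scheme(s, t)
  expect_equal(tr$conc[, "A"], 1e-6 * exp(-k * t), tolerance = 1e-6)
  expect_equal(tr$conc[, "B"], 1e-6 * (1 - exp(-k * t)), tolerance = 1e-6)
})

test_that("consecutive first-order kinetics peak at the analytic time", {
  k1 <- 2e6   # pseudo-first-order: 1e10 M-1 s-1 at 0.2 mM
  k2 <- 5.6e5
  s <- reaction_scheme(c("A", "B", "C"),
                       list(reaction("A", "B", k1), reaction("B", "C", k2)),
                       initial = c(A = 1e-6))
  t <- seq(1e-8, 1e-5, length.out = 400)
  tr <- simulate_scheme(s, t)
  t_analytic <- log(k1 / k2) / (k1 - k2)  # ~0.884 us
  prof <- trace_to_yields(tr, 11)
  expect_lte(abs(species_tmax(prof, "B") - t_analytic), diff(t)[1])
  # closed-form B(t) check at 1e-6 relative accuracy
  b_exact <- 1e-6 * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  expect_equal(tr$conc[, "B"], b_exact, tolerance = 1e-6)
})

test_that("radical count is conserved once sinks are disabled", {
  s <- scheme_compound1(list(k_rr = 0))
  t <- exp(seq(log(1e-8), log(1.7e-4), length.out = 50))
  tr <- simulate_scheme(s, t)
  radicals <- c("HO", "HOS", "Scat", "SS", "SN", "aS", "aC1", "aC2")
  tot <- rowSums(tr$conc[, radicals])
  expect_equal(tot, rep(tot[1], length(tot)), tolerance = 1e-7)
  expect_true(all(tr$conc > -1e-12))
})

test_that("trace and yield conversions are mutually inverse", {
  s <- scheme_compound1()
  tr <- simulate_scheme(s, exp(seq(log(2e-7), log(1.7e-4), length.out = 30)))
  prof <- trace_to_yields(tr, 11)
  back <- g_to_concentration(prof$g, 11)
  expect_equal(unname(back), unname(tr$conc[, colnames(prof$g)]),
               tolerance = 1e-12)
  # conc 6.16 uM at 11 Gy corresponds to G = 0.56
  one <- yield_profile(1e-6, matrix(6.16e-6 / (11 * 1e-6), 1,
                                    dimnames = list(NULL, "HO")))
  expect_equal(unname(one$g[1, 1]), 0.56)
})

test_that("species_tmax obeys its tie and error rules", {
  p <- yield_profile(c(1, 2, 3) * 1e-6,
                     matrix(c(3, 2, 1, 0, 0, 0), 3,
                            dimnames = list(NULL, c("dec", "flat"))))
  expect_equal(species_tmax(p, "dec"), 1e-6)  # monotone decay -> first point
  expect_warning(t0 <- species_tmax(p, "flat"), "flat")
  expect_equal(t0, 1e-6)
  expect_error(species_tmax(p, "nope"), "not in profile")
})

test_that("compound contrasts hold on the default schemes", {
  t <- exp(seq(log(2e-7), log(1.7e-4), length.out = 60))
  p1 <- trace_to_yields(simulate_scheme(scheme_compound1(), t), 11)
  p2 <- trace_to_yields(simulate_scheme(scheme_compound2(), t), 11)
  # HOS maximum: earlier and lower for the S-methyl-cysteine derivative
  expect_lt(species_tmax(p2, "HOS"), species_tmax(p1, "HOS"))
  expect_lt(max(p2$g[, "HOS"]), max(p1$g[, "HOS"]))
  # SS stays negligible (< 5% of the radical pool) for compound 2
  obs <- p2$g[, compound_species(2)]
  expect_true(all(obs[, "SS"] <= 0.05 * rowSums(obs)))
  # aS is the most abundant compound-1 species from 10 us onward
  obs1 <- p1$g[, compound_species(1)]
  late <- t >= 1e-5
  expect_true(all(colnames(obs1)[apply(obs1[late, ], 1, which.max)] == "aS"))
})

test_that("k_d is recoverable from a noisy HOS yield trace", {
  t <- exp(seq(log(2e-7), log(2e-5), length.out = 40))
  true_prof <- trace_to_yields(simulate_scheme(scheme_compound1(), t), 11)
  hos <- true_prof$g[, "HOS"]
  set.seed(11)
  noisy <- hos + rnorm(length(hos), 0, 0.005)
  sse <- function(kd) {
    p <- trace_to_yields(simulate_scheme(scheme_compound1(list(k_d = kd)), t),
                         11)
    sum((p$g[, "HOS"] - noisy)^2)
  }
  # coarse log grid, then golden-section refinement
  grid_k <- 10^seq(4.8, 6.5, length.out = 12)
  k0 <- grid_k[which.min(vapply(grid_k, sse, numeric(1)))]
  opt <- stats::optimize(function(lk) sse(exp(lk)),
                         interval = log(c(k0 / 3, k0 * 3)))
  expect_lt(abs(exp(opt$minimum) - 5.6e5) / 5.6e5, 0.10)
})

test_that("merged H-atom fragment stays inert without H atoms", {
  sc <- merge_schemes(scheme_compound1(), scheme_h_atom(1, list(g_h = 0)))
  tr <- simulate_scheme(sc, exp(seq(log(2e-7), log(1e-4), length.out = 20)))
  expect_true(all(tr$conc[, c("SuH", "CH3S", "Desulf")] < 1e-18))
})
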