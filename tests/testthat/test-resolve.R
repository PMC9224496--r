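lib <- default_library(default_grid)

test_that("OD to G*eps conversion is the dosimetry transform", {
  od <- matrix(0, 2, length(default_grid))
  s <- transient_series(default_grid, c(1e-6, 2e-6), od, dose = 11)
  expect_true(all(od_to_geps(s) == 0))

  # single-species slice built forward through Beer-Lambert at 11 Gy
  g_true <- 0.33
  eps <- lib$entries$HOS$eps
  od1 <- matrix(eps * g_true * 1e-6 * 11, 1)
  s1 <- transient_series(default_grid, 1e-6, od1, dose = 11, path = 1)
  geps <- od_to_geps(s1)
  expect_equal(geps[1, default_grid == 340], 0.33 * 3400)

  # scaling dose and OD together leaves G*eps unchanged
  s2 <- transient_series(default_grid, 1e-6, 3 * od1, dose = 33)
  expect_equal(od_to_geps(s2), geps)
})

test_that("a single-component slice is recovered identically", {
  geps <- 0.33 * lib$entries$HOS$eps
  fit <- resolve_slice(geps, lib)
  expect_equal(unname(fit$g["HOS"]), 0.33, tolerance = 1e-10)
  expect_true(all(fit$g[setdiff(names(fit$g), "HOS")] < 1e-10))
})

test_that("the reported compound-1 4 us mixture is recovered exactly", {
  g <- c(HOS = 0.12, aC1 = 0.09, aS = 0.14, SS = 0.10, SN = 0.08,
         aC2 = 0.03)
  geps <- drop(library_matrix(lib, names(g)) %*% g)
  fit <- resolve_slice(geps, lib, allowed = compound_species(1))
  expect_equal(fit$g[names(g)], g, tolerance = 1e-7)
  expect_lt(fit$residual_rms, 1e-7)
})

test_that("NNLS matches the unconstrained solve on interior solutions", {
  g <- c(HOS = 0.12, aC1 = 0.09, aS = 0.14, SS = 0.10, SN = 0.08,
         aC2 = 0.03)
  geps <- drop(library_matrix(lib, names(g)) %*% g)
  nn <- resolve_slice(geps, lib, allowed = names(g))
  ols <- resolve_slice(geps, lib, allowed = names(g), nonneg = FALSE)
  expect_equal(nn$g[names(g)], ols$g[names(g)], tolerance = 1e-9)
})

test_that("yields are never negative, even on pure-noise input", {
  set.seed(42)
  for (i in 1:20) {
    geps <- rnorm(length(default_grid), 0, 50)
    fit <- resolve_slice(geps, lib, allowed = compound_species(1))
    expect_true(all(fit$g >= 0))
  }
})

test_that("noisy single-slice recovery is accurate on average", {
  g <- c(HOS = 0.12, aC1 = 0.09, aS = 0.14, SS = 0.10, SN = 0.08,
         aC2 = 0.03)
  clean <- drop(library_matrix(lib, names(g)) %*% g)
  set.seed(7)
  err <- replicate(100, {
    fit <- resolve_slice(clean + rnorm(length(clean), 0, 20), lib,
                         allowed = compound_species(1))
    abs(fit$g[names(g)] - g)
  })
  expect_lt(mean(err), 0.02)
})

test_that("adding the true species never increases the residual", {
  g <- c(HOS = 0.2, aS = 0.1)
  geps <- drop(library_matrix(lib, names(g)) %*% g)
  without <- resolve_slice(geps, lib, allowed = c("HOS", "SS", "SN"))
  with_all <- resolve_slice(geps, lib, allowed = c("HOS", "SS", "SN", "aS"))
  expect_lte(with_all$residual_rms, without$residual_rms + 1e-12)
})

test_that("resolve_series round-trips a kinetics-derived profile", {
  spec <- synthetic_spec(compound = 1, noise_sd_od = 0)
  ds <- make_dataset(spec)
  fit <- resolve_series(ds$series, lib, allowed = compound_species(1))
  err <- abs(coef(fit)[, compound_species(1)] - ds$true_profile$g)
  expect_lt(max(err), 0.01)
  # argmax of the recovered HOS trace matches the generating trace
  t_fit <- species_tmax(fit, "HOS")
  t_true <- species_tmax(ds$true_profile, "HOS")
  expect_equal(t_fit, t_true)
})

test_that("fit object methods are consistent", {
  spec <- synthetic_spec(compound = 1, seed = 5)
  ds <- make_dataset(spec)
  fit <- resolve_series(ds$series, lib, allowed = compound_species(1))
  expect_s3_class(fit, "yield_fit")
  expect_equal(dim(coef(fit)), c(length(fit$times), 7))
  expect_equal(fitted(fit) + residuals(fit), fit$geps, tolerance = 1e-10)
  expect_output(print(fit), "non-negative least squares")
  sm <- summary(fit, expected_g = schuler_g(2e-4))
  expect_true(all(c("total_g", "balance_ratio") %in% names(sm)))
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()
})

test_that("resolution fails cleanly on bad inputs", {
  geps <- rep(0, length(default_grid))
  expect_error(resolve_slice(geps, lib, allowed = character()), "empty")
  expect_error(resolve_slice(geps[1:5], lib), "grid")
  few <- default_grid[1:8]  # fewer than 2x species wavelengths
  expect_error(
    resolve_slice(rep(0, 8), default_library(few), compound_species(1)),
    "twice as many")
})

test_that("percentage contributions reproduce the reported rounding", {
  p <- percentage_contributions(c(HOS = 0.27, aC1 = 0.08, SS = 0.02))
  expect_equal(unname(p$percent), c(73, 22, 5))
  expect_equal(sum(p$fraction), 1)
  # 0.33 of a 0.46 total
  p2 <- percentage_contributions(c(a = 0.33, b = 0.46 - 0.33))
  expect_equal(unname(p2$percent[1]), 72)
  expect_equal(unname(percentage_contributions(c(x = 0.5))$percent), 100)
  expect_error(percentage_contributions(c(a = 0, b = 0)), "zero")
})

test_that("material balance matches the reported totals", {
  b1 <- material_balance(c(0.12, 0.09, 0.14, 0.10, 0.08, 0.03), 0.557)
  expect_equal(b1$total, 0.56)
  expect_equal(b1$ratio, 1, tolerance = 0.01)
  b2 <- material_balance(c(0.07, 0.08, 0.23, 0.12, 0.10), 0.557)
  expect_equal(b2$total, 0.60)
  b0 <- material_balance(numeric(0), 0.557)
  expect_equal(c(b0$total, b0$ratio), c(0, 0))
})
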