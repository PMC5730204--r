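test_that("residual-sd calibration solves the heritability identity", {
  map <- tiny_map(8)
  g <- simulate_ril_genotypes(map, 400, seed = 3)
  arch <- random_architecture(8, 3, seed = 4)
  varG <- var(expected_Z(g, arch, "Z1"))
  # h = 1/2, c = 2, m = 1  =>  sigma_e^2 = VarG / 2
  s1 <- calibrate_residual_sd(arch, g, h = 0.5, m = 1, which = "Z1")
  expect_equal(s1^2, varG / 2)
  # doubling m at fixed h doubles sigma_e^2
  s2 <- calibrate_residual_sd(arch, g, h = 0.5, m = 2, which = "Z1")
  expect_equal(s2^2, 2 * s1^2)
  # closed form with c = 3 for Z4
  s4 <- calibrate_residual_sd(arch, g, h = 0.8, m = 10, which = "Z4")
  expect_equal(s4^2, var(expected_Z(g, arch, "Z4")) * 0.2 * 10 / (0.8 * 3))
  # near-1 heritability drives sigma_e to 0
  expect_lt(calibrate_residual_sd(arch, g, h = 1 - 1e-9, m = 1), 1e-3)
  expect_error(calibrate_residual_sd(arch, g, h = 1.2, m = 1), "0, 1")
  null <- qtl_architecture(0, data.frame(marker = 1, a = 0, d = 0))
  expect_error(calibrate_residual_sd(null, g, h = 0.5, m = 1), "degenerate")
})

test_that("noiseless simulation reproduces the oracle exactly, with identities", {
  map <- tiny_map(8)
  g <- simulate_ril_genotypes(map, 100, seed = 6)
  arch <- random_architecture(8, 3, seed = 7)
  ph <- simulate_phenotypes(arch, g, m = 3, seed = 8, sigma_e = 0,
                            transformations = c("Z1", "Z2", "Z3", "Z4"))
  for (z in c("Z1", "Z2", "Z3", "Z4"))
    expect_equal(ph$Z[[z]], expected_Z(g, arch, z))
  # exact linear identities among observed transformations
  ph2 <- simulate_phenotypes(arch, g, h = 0.5, m = 2, seed = 9,
                             transformations = c("Z1", "Z2", "Z3", "Z4"))
  expect_equal(ph2$Z$Z4, ph2$Z$Z1 - ph2$family_means$L4)
  expect_equal(ph2$Z$Z3, ph2$Z$Z1 - 2 * ph2$family_means$L3)
  # family means equal the mean of their replicates
  expect_equal(rowMeans(ph2$family_obs$L1), ph2$family_means$L1)
})

test_that("same seed gives identical data; realized heritability hits its target", {
  map <- tiny_map(8)
  g <- simulate_ril_genotypes(map, 200, seed = 10)
  arch <- random_architecture(8, 3, seed = 11)
  a <- simulate_phenotypes(arch, g, h = 0.5, m = 4, seed = 12)
  b <- simulate_phenotypes(arch, g, h = 0.5, m = 4, seed = 12)
  expect_identical(a, b)
  # realized h at large n: Var(genetic) / Var(observed) ~ target
  gbig <- simulate_ril_genotypes(map, 1e4, seed = 13)
  for (h in c(0.8, 0.2)) {
    ph <- simulate_phenotypes(arch, gbig, h = h, m = 5, seed = 14,
                              transformations = "Z1")
    gval <- expected_Z(gbig, arch, "Z1")
    realized <- var(gval) / var(ph$Z$Z1)
    se <- 3 * (1 - h) / sqrt(1e4)  # generous Monte Carlo band
    expect_lt(abs(realized - h), 3 * 0.02 + se)
  }
})
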