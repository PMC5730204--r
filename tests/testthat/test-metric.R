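test_that("F-infinity codes are +1/0/-1 additive, 0/1/0 dominance", {
  expect_equal(fq_codes(c("MM", "Mm", "mm")),
               cbind(x_a = c(1, 0, -1), x_d = c(0, 1, 0)))
  expect_error(fq_codes("MN"), "invalid genotype")
})

test_that("genotypic values of the benchmark two-QTL preset enumerate correctly", {
  full <- preset_architecture()
  arch <- qtl_architecture(0, full$qtl[1:2, ], full$pairs[1, ])
  self_MM <- progeny_distribution(rep(1, 100), "SELF")
  expect_equal(genotypic_value(self_MM, arch), 1.8 + 2.8 + 2.7)  # 7.3
  het <- matrix(0, 100, 3, dimnames = list(NULL, c("MM", "Mm", "mm")))
  het[, "Mm"] <- 1
  expect_equal(genotypic_value(het, arch), 3.2 - 1.5 - 0.5)      # 1.2
  null <- qtl_architecture(mu = 2.5,
                           qtl = data.frame(marker = 1:2, a = 0, d = 0))
  expect_equal(genotypic_value(self_MM, null), 2.5)
  expect_error(genotypic_value(self_MM[1:10, ], arch), "missing")
})

test_that("expected transformation values match hand enumeration of the preset", {
  full <- preset_architecture()
  arch <- qtl_architecture(0, full$qtl[1:2, ], full$pairs[1, ])
  MMMM <- matrix(1, 1, 100)
  expect_equal(expected_Z(MMMM, arch, "Z4"), 0 + 3.2 - 1.5 - 0.5)     # 1.2
  expect_equal(expected_Z(MMMM, arch, "Z1"),
               2 * 0 + 1.8 + 2.8 + 3.2 - 1.5 + 2.7 - 0.5)             # 8.5
  MMmm <- MMMM; MMmm[36] <- -1
  expect_equal(expected_Z(MMmm, arch, "Z2"),
               1.8 + 2.8 - 3.2 - 1.5 + 3.4 + 1.0)                     # 4.3
  expect_error(expected_Z(matrix(0, 1, 100), arch, "Z1"), "homozygous")
})

test_that("oracle equals the augmented-coding linear predictor for every genotype class", {
  # all four two-locus classes, several random effect vectors
  G <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (seed in 1:5) {
    arch <- random_architecture(2, 2, seed = seed)
    ae <- augmented_effects(arch)
    x1 <- G[, 1]; x2 <- G[, 2]
    z1_pred <- oracle_intercept(arch, "Z1") +
      x1 * ae$qtl$a_star[1] + x2 * ae$qtl$a_star[2] +
      (1 + x1 * x2) / 2 * ae$pairs$i_sum
    expect_equal(expected_Z(G, arch, "Z1"), z1_pred)
    z2_pred <- oracle_intercept(arch, "Z2") +
      (-x1) * ae$qtl$d_star[1] + (-x2) * ae$qtl$d_star[2] +
      (1 - x1 * x2) / 2 * ae$pairs$i_tilde
    expect_equal(expected_Z(G, arch, "Z2"), z2_pred)
    # Z4: (-1/2, 1/2, 1/2, -1/2) codes for i_aa - i_dd, (0, 1, -1, 0) for
    # i_ad - i_da, with the intercept absorbing mu + d1 + d2 + (iaa+idd)/2
    z4_pred <- oracle_intercept(arch, "Z4") +
      (-x1 * x2 / 2) * ae$pairs$i_diff + (x1 - x2) / 2 * ae$pairs$i_asym
    expect_equal(expected_Z(G, arch, "Z4"), z4_pred)
  }
})

test_that("without epistasis the augmented effects collapse to raw a and d", {
  arch <- qtl_architecture(1, data.frame(marker = c(2, 5),
                                         a = c(1.1, -0.4), d = c(0.3, 2)))
  ae <- augmented_effects(arch)
  expect_equal(ae$qtl$a_star, arch$qtl$a)
  expect_equal(ae$qtl$d_star, arch$qtl$d)
})
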