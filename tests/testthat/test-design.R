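test_that("column counts follow p = q + q(q-1)/2 for Z1/Z2 and 2 pairs-worth for Z4", {
  g5 <- matrix(sample(c(-1, 1), 3 * 5, TRUE), 3, 5)
  for (q in c(5)) {
    expect_equal(ncol(build_design(g5, "Z1")), q + q * (q - 1) / 2)
    expect_equal(ncol(build_design(g5, "Z2")), q + q * (q - 1) / 2)
    expect_equal(ncol(build_design(g5, "Z4")), q * (q - 1))
  }
  g100 <- matrix(rep(1, 2 * 100), 2, 100)
  expect_equal(ncol(build_design(g100, "Z1")), 5050)
  expect_error(build_design(matrix(0, 2, 3), "Z1"), "homozygous")
})

test_that("codings follow the coefficient conventions for the MM/mm line", {
  g <- matrix(c(1, -1), 1, 2)  # MM at k, mm at l
  X1 <- build_design(g, "Z1")
  expect_equal(as.numeric(X1), c(1, -1, 0))            # x_a*k, x_a*l, x_i<->
  X2 <- build_design(g, "Z2")
  expect_equal(as.numeric(X2), c(-1, 1, 1))            # u_d*k, u_d*l, u_i~
  X4 <- build_design(g, "Z4")                          # effect scale
  expect_equal(as.numeric(X4), c(0.5, 1))              # w_i->, w_i<-
  X4p <- build_design(g, "Z4", scale = "printed")      # printed +-1 codes
  expect_equal(as.numeric(X4p), c(1, 1))
})

test_that("interaction codings are (1 +/- x_k x_l)/2 for every random line", {
  set.seed(21)
  g <- matrix(sample(c(-1, 1), 40 * 6, TRUE), 40, 6)
  X1 <- build_design(g, "Z1"); X2 <- build_design(g, "Z2")
  t1 <- attr(X1, "terms")
  for (j in which(t1$type == "i_sum")) {
    prod <- g[, t1$k[j]] * g[, t1$l[j]]
    expect_equal(unname(X1[, j]), (1 + prod) / 2)
    expect_equal(unname(X2[, j]), (1 - prod) / 2)
  }
  # product coding is the stated affine transform of the standard one
  Xp <- build_design(g, "Z1", coding = "product")
  j <- which(t1$type == "i_sum")[1]
  expect_equal(unname(Xp[, j]), 2 * unname(X1[, j]) - 1)
})

test_that("noiseless regression on the design recovers augmented effects exactly", {
  map <- tiny_map(9)
  g <- simulate_ril_genotypes(map, 250, seed = 22)
  for (seed in 1:3) {
    arch <- random_architecture(9, 3, seed = seed)
    ae <- augmented_effects(arch)
    for (z in c("Z1", "Z2")) {
      y <- expected_Z(g, arch, z)
      X <- build_design(g, z)
      fit <- lm(y ~ unclass(X))
      co <- coef(fit)[-1]; co[is.na(co)] <- 0
      terms <- attr(X, "terms")
      truth <- numeric(ncol(X))
      if (z == "Z1") {
        truth[match(ae$qtl$marker, terms$k[terms$type == "a_star"])] <- ae$qtl$a_star
        pk <- which(terms$type == "i_sum")
        truth[pk[match(paste(ae$pairs$k, ae$pairs$l),
                       paste(terms$k[pk], terms$l[pk]))]] <- ae$pairs$i_sum
      } else {
        truth[match(ae$qtl$marker, terms$k[terms$type == "d_star"])] <- ae$qtl$d_star
        pk <- which(terms$type == "i_tilde")
        truth[pk[match(paste(ae$pairs$k, ae$pairs$l),
                       paste(terms$k[pk], terms$l[pk]))]] <- ae$pairs$i_tilde
      }
      expect_equal(unname(co), truth, tolerance = 1e-10)
      expect_lt(max(abs(resid(fit))), 1e-9)
      expect_equal(unname(coef(fit)[1]), oracle_intercept(arch, z),
                   tolerance = 1e-10)
    }
    # Z4: the full interaction blocks are intentionally oversaturated, so
    # exact identification is checked on the true-support columns of a
    # disjoint-pair layout (chained pairs alias the asymmetric block)
    arch <- random_architecture(9, 4, seed = seed, pairs = "disjoint")
    ae <- augmented_effects(arch)
    y4 <- expected_Z(g, arch, "Z4")
    X4 <- build_design(g, "Z4")
    t4 <- attr(X4, "terms")
    keep <- which(paste(t4$k, t4$l) %in% paste(ae$pairs$k, ae$pairs$l))
    fit4 <- lm(y4 ~ X4[, keep])
    expect_lt(max(abs(resid(fit4))), 1e-9)
    co4 <- coef(fit4)[-1]
    tt <- t4[keep, ]
    truth4 <- ifelse(tt$type == "i_diff",
                     ae$pairs$i_diff[match(paste(tt$k, tt$l),
                                           paste(ae$pairs$k, ae$pairs$l))],
                     ae$pairs$i_asym[match(paste(tt$k, tt$l),
                                           paste(ae$pairs$k, ae$pairs$l))])
    expect_equal(unname(co4), truth4, tolerance = 1e-10)
  }
})

test_that("Z5/Z6 enumerated codings reproduce the oracle expectations", {
  map <- tiny_map(7)
  g <- simulate_ril_genotypes(map, 120, seed = 23)
  arch <- random_architecture(7, 3, seed = 9)
  for (z in c("Z5", "Z6")) {
    X <- attcqtl::build_design(g, z)
    terms <- attr(X, "terms")
    beta <- numeric(ncol(X))
    for (i in seq_len(nrow(arch$qtl)))
      beta[terms$type == "a" & terms$k == arch$qtl$marker[i]] <- arch$qtl$a[i]
    for (i in seq_len(nrow(arch$pairs))) {
      sel <- !is.na(terms$l) & terms$k == arch$pairs$k[i] &
        terms$l == arch$pairs$l[i]
      beta[sel & terms$type == "i_aa"] <- arch$pairs$iaa[i]
      beta[sel & terms$type == "i_ad"] <- arch$pairs$iad[i]
      beta[sel & terms$type == "i_da"] <- arch$pairs$ida[i]
      beta[sel & terms$type == "i_dd"] <- arch$pairs$idd[i]
    }
    pred <- oracle_intercept(arch, z) + unclass(X) %*% beta
    expect_equal(as.numeric(pred), expected_Z(g, arch, z))
  }
})
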