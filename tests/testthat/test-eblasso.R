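test_that("a single strong effect is retained with t above the filter", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(sample(c(-1, 1), 150 * 400, TRUE), 150, 400)
    y <- 5 * X[, 42] + rnorm(150)
    fit <- eb_lasso_fit(y, X)
    expect_true(42 %in% fit$active)
    expect_gt(fit$t[42], 2)
    # excluded coefficients are exactly zero; active set stays sparse
    expect_true(all(fit$beta[-fit$active] == 0))
    expect_lt(length(fit$active), 150 - 2)
  }
})

test_that("the weak-shrinkage limit approaches ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(300 * 10), 300, 10)
  beta <- rnorm(10, 0, 3)
  y <- X %*% beta + rnorm(300, 0, 0.5)
  fit <- eb_lasso_fit(y, X, a = 0.01, b = 1000)
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(fit$beta), unname(ols), tolerance = 0.02)
})

test_that("pure-noise oversaturated fits rarely report a significant term", {
  hits <- sapply(1:10, function(i) {
    g <- simulate_ril_genotypes(default_marker_map(), 200, seed = 400 + i)
    set.seed(500 + i)
    y <- rnorm(200)
    X <- build_design(g, "Z1")
    f <- eb_lasso_fit(y, X)
    r <- which(f$t > 2)
    if (!length(r)) 0L else nrow(refit_and_test(y, X, r))
  })
  expect_lte(sum(hits > 0), 1)
})

test_that("the closed-form prior-variance update maximises the objective", {
  for (a in c(0.05, 0.5, 1)) for (b in c(3e-4, 0.1)) {
    for (case in list(c(s = 2, q = 3), c(s = 0.5, q = 0.2), c(s = 10, q = -6),
                      c(s = 200, q = 60))) {
      u_cf <- attcqtl:::.eb_opt_variance(case["s"], case["q"], a, b)
      f <- function(u) attcqtl:::.eb_loglik(u, case["s"], case["q"]) +
        attcqtl:::.eb_logprior(u, a, b)
      u_num <- optimize(f, c(1e-10, 1e5), maximum = TRUE)$maximum
      if (u_cf > 0) {
        expect_gte(f(u_cf), f(u_num) - 1e-6)
      } else {
        # no positive stationary point: the objective should not beat u -> 0
        expect_lte(f(u_num), max(f(1e-10), 0) + 1e-6)
      }
    }
  }
})

test_that("hyperparameter selection is deterministic and honours the grid", {
  set.seed(9)
  X <- matrix(sample(c(-1, 1), 120 * 50, TRUE), 120, 50)
  y <- 3 * X[, 7] + rnorm(120)
  one <- data.frame(a = 0.5, b = 0.1)
  expect_equal(select_hyperparameters(y, X, grid = one)[c("a", "b")],
               list(a = 0.5, b = 0.1))
  grid <- data.frame(a = c(0.1, 1), b = c(0.1, 3e-4))
  s1 <- select_hyperparameters(y, X, grid = grid, seed = 4)
  s2 <- select_hyperparameters(y, X, grid = grid, seed = 4)
  expect_identical(s1, s2)
  expect_equal(min(s1$grid$cv_error),
               s1$grid$cv_error[s1$grid$a == s1$a & s1$grid$b == s1$b])
  expect_error(select_hyperparameters(y, X, grid = grid[0, ]), "empty")
  expect_error(select_hyperparameters(y[1:2], X[1:2, ], folds = 3), "folds")
})

test_that("refit interpolates noiseless data and orders terms consistently", {
  set.seed(10)
  X <- matrix(sample(c(-1, 1), 80 * 20, TRUE), 80, 20)
  beta <- c(3, -2, 1.5)
  y <- X[, c(2, 9, 17)] %*% beta
  sc <- refit_and_test(y, X, c(2, 9, 17), lod_threshold = -Inf)
  expect_equal(sc$estimate, beta)
  # column-order invariance of the estimates
  sc2 <- refit_and_test(y, X, c(17, 2, 9), lod_threshold = -Inf)
  expect_equal(sc2$estimate, beta)
  # LOD grows with sample size for a fixed signal-to-noise ratio
  lods <- sapply(c(100, 200, 400), function(n) {
    set.seed(11)
    Xn <- matrix(sample(c(-1, 1), n * 5, TRUE), n, 5)
    yn <- 2 * Xn[, 3] + rnorm(n)
    refit_and_test(yn, Xn, 3, lod_threshold = -Inf)$lod
  })
  expect_true(all(diff(lods) > 0))
})

test_that("duplicated and aliased retained columns are collapsed", {
  set.seed(12)
  x <- sample(c(-1, 1), 60, TRUE)
  X <- cbind(x, x, rnorm(60))
  y <- 2 * x + rnorm(60, 0, 0.1)
  expect_message(sc <- refit_and_test(y, X, 1:3, lod_threshold = -Inf),
                 "duplicated")
  expect_equal(nrow(sc), 2)
  # a column equal to a linear combination of intercept and another column
  X2 <- cbind(x, 1 - 2 * x, rnorm(60))
  expect_message(sc2 <- refit_and_test(y, X2, 1:3, lod_threshold = -Inf),
                 "aliased")
  expect_equal(nrow(sc2), 2)
})

test_that("the lasso backend finds the same strong term through the same filters", {
  skip_if_not_installed("glmnet")
  map <- tiny_map(20, spacing = 20)
  g <- simulate_ril_genotypes(map, 300, seed = 30)
  arch <- qtl_architecture(qtl = data.frame(marker = 7, a = 2, d = 0))
  ph <- simulate_phenotypes(arch, g, h = 0.8, m = 5, seed = 31,
                            transformations = "Z1")
  sc <- scan_transformation(ph$Z$Z1, g, "Z1", backend = "lasso", seed = 5)
  expect_true("a_star:7" %in% sc$term)
})
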