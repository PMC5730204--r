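test_that("pair dissection inverts the augmented definitions", {
  # benchmark pair 1: augmented (2.2, 4.4, 3.2, 2.4) -> (2.7, 3.4, 1.0, -0.5)
  expect_equal(dissect_pair(2.2, 4.4, 3.2, 2.4),
               data.frame(iaa = 2.7, iad = 3.4, ida = 1.0, idd = -0.5))
  # benchmark pair 2: (2.2, -5.4, -3.6, 2.2) -> (-0.7, -1.6, -3.8, 2.9)
  expect_equal(dissect_pair(2.2, -5.4, -3.6, 2.2),
               data.frame(iaa = -0.7, iad = -1.6, ida = -3.8, idd = 2.9))
  expect_equal(unlist(dissect_pair(0, 0, 0, 0)), c(iaa = 0, iad = 0, ida = 0, idd = 0))
})

test_that("main-effect dissection removes the epistatic contamination", {
  pair <- data.frame(iaa = 2.7, iad = 3.4, ida = 1.0, idd = -0.5)
  expect_equal(dissect_main(3.0, 1.6, pair, k_first = TRUE),
               c(a = 1.8, d = 3.2))
  # second member of the pair: asymmetric terms swap roles
  expect_equal(dissect_main(1.6, -3.1, pair, k_first = FALSE),
               c(a = 2.8, d = -1.5))
  expect_equal(dissect_main(0.7, -0.2), c(a = 0.7, d = -0.2))
})

test_that("dominance-degree classes follow the printed cutpoints exactly", {
  expect_equal(classify_dominance(0.00, 2.09), "A")
  expect_equal(classify_dominance(1.86, 0.00), "OD")
  expect_equal(classify_dominance(1.89, -1.89), "D")   # ratio exactly 1
  # left-closed boundaries partition [0, Inf)
  expect_equal(classify_dominance(c(0.19, 0.2, 0.79, 0.8, 1.19, 1.2), 1),
               c("A", "PD", "PD", "D", "D", "OD"))
  expect_true(is.na(classify_dominance(0, 0)))
  expect_error(classify_dominance(Inf, 1), "finite")
})

test_that("forward augmentation then integration round-trips exactly", {
  # includes architectures with >= 3 interacting QTL and multi-partner sums
  for (seed in 1:6) {
    arch <- random_architecture(30, n_qtl = 2 + seed %% 3 + 2, seed = seed)
    scans <- oracle_scans(arch)
    dis <- integrate_scans(scans$Z1, scans$Z2, scans$Z4)
    qm <- match(arch$qtl$marker, dis$qtl$marker)
    expect_equal(dis$qtl$a[qm], arch$qtl$a)
    expect_equal(dis$qtl$d[qm], arch$qtl$d)
    pm <- match(paste(arch$pairs$k, arch$pairs$l),
                paste(dis$pairs$k, dis$pairs$l))
    expect_equal(dis$pairs$iaa[pm], arch$pairs$iaa)
    expect_equal(dis$pairs$iad[pm], arch$pairs$iad)
    expect_equal(dis$pairs$ida[pm], arch$pairs$ida)
    expect_equal(dis$pairs$idd[pm], arch$pairs$idd)
    expect_false(any(dis$pairs$incomplete))
  }
})

test_that("missing augmented components are zero-imputed and flagged", {
  s1 <- fake_scan("Z1", "i_sum", 4, 9, 2.2)       # pair seen only in Z1
  empty <- fake_scan("Z2", "d_star", integer(0), estimate = numeric(0))
  dis <- integrate_scans(s1, empty, empty)
  expect_true(dis$pairs$incomplete)
  expect_equal(dis$pairs$iaa, 1.1)                 # i_sum / 2
  expect_equal(dis$pairs$idd, 1.1)
  expect_equal(dis$pairs$iad, 0)
  # the two member QTL appear with zero-imputed augmented mains
  expect_setequal(dis$qtl$marker, c(4, 9))
  expect_true(all(dis$qtl$incomplete))
  # drop_incomplete removes the partial quartet
  dis2 <- integrate_scans(s1, empty, empty, drop_incomplete = TRUE)
  expect_equal(nrow(dis2$pairs), 0)
  # empty scans give an empty result
  dis3 <- integrate_scans(empty, empty, empty)
  expect_equal(nrow(dis3$qtl), 0)
  expect_equal(nrow(dis3$pairs), 0)
})

test_that("map annotation attaches chromosome and marker names", {
  map <- two_chr_map()
  s1 <- fake_scan("Z1", "a_star", 2, estimate = 1)
  empty <- fake_scan("Z2", "d_star", integer(0), estimate = numeric(0))
  dis <- integrate_scans(s1, empty, empty, map = map)
  expect_equal(dis$qtl$chr, "C1")
  expect_equal(dis$qtl$marker_name, "M2")
})
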