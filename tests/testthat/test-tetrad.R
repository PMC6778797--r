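test_that("forward chromatid-sampling model matches direct summation", {
  expect_equal(unname(forward_gamete_distribution(c(1, 0, 0, 0))),
               c(1, 0, 0, 0))
  expect_equal(unname(forward_gamete_distribution(c(0, 1, 0, 0))),
               c(0.5, 0.5, 0, 0))
  # direct summation of a_j = sum_n C(n,j) 2^-n E_n
  E <- c(0.205, 0.685, 0.107, 0.004)
  a_oracle <- vapply(0:3, function(j)
    sum(vapply(j:3, function(n) choose(n, j) * 2^-n * E[n + 1], 0)), 0)
  expect_equal(unname(forward_gamete_distribution(E)), a_oracle)
  expect_equal(unname(forward_gamete_distribution(E)),
               c(0.57475, 0.39750, 0.02825, 0.00050))
  expect_error(forward_gamete_distribution(c(-0.1, 1.1)), "nonnegative")
})

test_that("Weinstein inversion solves the triangular system exactly", {
  expect_equal(unname(weinstein_invert(c(1, 0, 0, 0))$E), c(1, 0, 0, 0))
  expect_equal(unname(weinstein_invert(c(0.5, 0.5, 0, 0))$E), c(0, 1, 0, 0))
  td <- weinstein_invert(c(0.57475, 0.39750, 0.02825, 0.00050))
  expect_equal(unname(td$E), c(0.205, 0.685, 0.107, 0.004),
               tolerance = 1e-12)
  expect_error(weinstein_invert(numeric(0)), "empty")
})

test_that("invert/forward are mutual identities and conserve mass (N <= 10)", {
  set.seed(91)
  for (N in c(1L, 3L, 6L, 10L)) {
    E <- stats::runif(N + 1L)
    E <- E / sum(E)
    a <- forward_gamete_distribution(E)
    expect_equal(unname(weinstein_invert(a)$E), E, tolerance = 1e-12)
    expect_equal(sum(a), sum(E), tolerance = 1e-12)
    # gamete mean = tetrad mean / 2 (each exchange on 2 of 4 chromatids)
    expect_equal(sum((0:N) * a), sum((0:N) * E) / 2, tolerance = 1e-12)
    # forward o invert identity, via the mixing matrix directly
    a2 <- stats::runif(N + 1L); a2 <- a2 / sum(a2)
    td <- suppressWarnings(weinstein_invert(a2))
    expect_equal(as.numeric(meiocross:::weinstein_matrix(N) %*% td$E),
                 a2, tolerance = 1e-12)
  }
})

test_that("closed-form inversion equals numerical matrix inversion", {
  for (N in 1:10) {
    M <- meiocross:::weinstein_matrix(N)
    set.seed(N)
    a <- stats::runif(N + 1L)
    closed <- suppressWarnings(weinstein_invert(a)$E)
    expect_equal(unname(closed), as.numeric(solve(M, a)), tolerance = 1e-10)
  }
})

test_that("tetrad moments reproduce the published summary arithmetic", {
  ref <- reference_tetrads()
  expect_equal(unname(tetrad_moments(ref$pse)["mean"]), 0.775)
  expect_equal(round(tetrad_moments(ref$mel)[["variance"]], 3), 0.319)
  expect_equal(unname(tetrad_moments(ref$"mei-218")["mean"]), 0.042)
  # printed-value tolerance: recomputation from rounded class frequencies
  # lands within one unit in the third decimal of the printed moments
  expect_equal(round(tetrad_moments(ref$mel)[["mean"]], 3), 0.911)
  expect_equal(round(tetrad_moments(ref$pse)[["variance"]], 3), 0.542)
  m0 <- tetrad_moments(c(1, 0, 0, 0))
  expect_equal(unname(m0[c("mean", "variance")]), c(0, 0))
  expect_true(is.na(m0[["relative_variance"]]))
})

test_that("fold-difference table reproduces the published pairwise columns", {
  ref <- reference_tetrads()
  ft <- fold_difference_table(ref[c("mel", "pse", "vir")])
  expect_equal(round(ft[["pse-mel"]], 2), c(1.90, -1.47, 1.16, 5.00))
  expect_equal(round(ft[["vir-mel"]], 2), c(4.32, -7.29, -7.13, 1.50))
  # E0 sits on a rounding boundary (0.885/0.389 = 2.275): compare
  # unrounded against the printed +2.27 with half-unit slack
  expect_equal(ft[["vir-pse"]][1], 2.27, tolerance = 0.005)
  expect_equal(round(ft[["vir-pse"]][2:4], 2), c(-4.97, -8.27, -3.33))
  same <- fold_difference_table(list(a = ref$mel, b = ref$mel))
  expect_true(all(same[["b-a"]] == 1))
  # zero class in either member -> undefined cell
  ft0 <- fold_difference_table(list(a = c(0.9, 0.1, 0), b = c(0.8, 0.1, 0.1)))
  expect_true(is.na(ft0[["b-a"]][3]))
})

test_that("negative class estimates are flagged, retained, and clippable", {
  # a1 > 0.5 forces E0 < 0 under the model
  expect_warning(td <- weinstein_invert(c(0.3, 0.7)), "negative")
  expect_true(td$negative)
  expect_lt(td$E[["E0"]], 0)
  cl <- constrain_nonnegative(td)
  expect_true(all(cl$E >= 0))
  expect_equal(sum(cl$E), sum(td$E), tolerance = 1e-12)
})

test_that("dispersion test calls direction from relative variance", {
  ref <- reference_tetrads()
  d <- dispersion_test(tetrad_distribution(ref$pse), n_tetrads = 2028)
  expect_identical(d$direction, "under")
  expect_equal(d$relative_variance, 0.6998, tolerance = 1e-3)
  expect_lt(d$p, 1e-10)
  d2 <- dispersion_test(tetrad_distribution(ref$vir), n_tetrads = 1304)
  expect_identical(d2$direction, "over")
  expect_gt(d2$relative_variance, 1)
  expect_error(dispersion_test(tetrad_distribution(c(1, 0)), n_tetrads = 10),
               "mean")
})

test_that("dispersion test accepts Poisson tetrad counts as null", {
  set.seed(202)
  n <- 20000L
  draws <- stats::rpois(n, 1)
  E_hat <- tabulate(draws + 1L, nbins = max(draws) + 1L) / n
  d <- dispersion_test(tetrad_distribution(E_hat), n_tetrads = n)
  expect_equal(d$relative_variance, 1, tolerance = 0.05)
  expect_gt(d$p, 0.001)
})

test_that("crossover-class comparison pools sparse classes and is exact on 2x2", {
  a <- make_tab(c(100L, 0L, 0L, 0L, 0L),
                c(a0 = 100L, a1 = 0L, a2 = 0L, a3 = 0L, a4 = 0L, a5 = 0L))
  b <- make_tab(c(0L, 100L, 0L, 0L, 0L),
                c(a0 = 0L, a1 = 100L, a2 = 0L, a3 = 0L, a4 = 0L, a5 = 0L))
  r <- compare_class_chi2(a, b)
  expect_equal(r$chi2, 200)
  expect_equal(r$df, 1)
  # sparse top classes get pooled so all expected counts >= 1
  c1 <- make_tab(c(60L, 0L, 0L, 0L, 0L),
                 c(a0 = 140L, a1 = 52L, a2 = 7L, a3 = 1L, a4 = 0L, a5 = 0L))
  c2 <- make_tab(c(60L, 0L, 0L, 0L, 0L),
                 c(a0 = 150L, a1 = 48L, a2 = 2L, a3 = 0L, a4 = 0L, a5 = 0L))
  r2 <- compare_class_chi2(c1, c2)
  expect_lte(r2$classes_used, 3L)
  expect_true(is.finite(r2$chi2))
  r0 <- compare_class_chi2(c1, c1)
  expect_equal(r0$chi2, 0)
  expect_error(compare_class_chi2(a, a), "degenerate")
})
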