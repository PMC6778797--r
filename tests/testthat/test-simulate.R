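test_that("config validation catches bad parameters before sampling", {
  m <- map6()
  expect_error(sim_config(m, model = "explicit"), "E vector")
  expect_error(sim_config(m, model = "explicit", E = c(-0.1, 1.1)),
               "E vector")
  expect_error(sim_config(m, model = "poisson"), "lambda")
  expect_error(sim_config(m, model = "counting", target_mean = NULL),
               "target_mean")
  expect_error(sim_config(m, model = "explicit", E = c(1, 0),
                          intensity = c(1, 1)), "per interval")
  expect_error(sim_config(m, model = "explicit", E = c(1, 0),
                          intensity = rep(0, 5)), "not all zero")
  expect_error(sim_config(m, model = "explicit", E = c(1, 0), seed = "x"),
               "seed")
})

test_that("the seed fully determines the simulated experiment", {
  cfg <- sim_config(map6(), n_crosses = 3, progeny_per_cross = c(40, 80),
                    model = "explicit", E = c(0.2, 0.6, 0.2), seed = 123)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$collection$crosses, s2$collection$crosses)
  expect_identical(s1$truth, s2$truth)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_progeny_table(s1$collection, p1)
  write_progeny_table(s2$collection, p2)
  expect_identical(readLines(p1), readLines(p2))
  cfg3 <- sim_config(map6(), n_crosses = 3, progeny_per_cross = c(40, 80),
                     model = "explicit", E = c(0.2, 0.6, 0.2), seed = 124)
  expect_false(identical(simulate_experiment(cfg3)$collection$crosses,
                         s1$collection$crosses))
})

test_that("degenerate exchange models produce the forced genotypes", {
  cfg <- sim_config(map6(), n_crosses = 2, progeny_per_cross = 30,
                    model = "explicit", E = c(1, 0, 0, 0), seed = 9)
  sim <- simulate_experiment(cfg)
  tab <- pool_crosses(sim$collection)
  expect_identical(unname(tab$class_counts), c(60L, rep(0L, 5)))
  expect_true(all(sim$truth$n_exchanges == 0L))
  # always exactly one exchange
  cfg1 <- sim_config(map6(), n_crosses = 1, progeny_per_cross = 400,
                     model = "explicit", E = c(0, 1), seed = 9)
  sim1 <- simulate_experiment(cfg1)
  expect_true(all(sim1$truth$n_exchanges == 1L))
  a <- pool_crosses(sim1$collection)$class_counts / 400
  expect_lt(abs(a[["a0"]] - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("exchange-count draws follow the configured model", {
  m <- map6()
  set.seed(1)
  cfgp <- sim_config(m, model = "poisson", lambda = 1, seed = 1)
  x <- draw_exchange_count(cfgp, 1e5)
  expect_lt(abs(mean(x) - 1), 0.011)
  # assurance: zero draws resampled away, conditional distribution kept
  cfga <- sim_config(m, model = "explicit", E = c(0.5, 0.3, 0.2),
                     assurance = TRUE, seed = 1)
  xa <- draw_exchange_count(cfga, 2e4)
  expect_true(all(xa >= 1L))
  expect_lt(abs(mean(xa == 1L) - 0.6), 3 * sqrt(0.24 / 2e4))
  cfgpa <- sim_config(m, model = "poisson", lambda = 1, assurance = TRUE,
                      seed = 1)
  xpa <- draw_exchange_count(cfgpa, 2e4)
  expect_true(all(xpa >= 1L))
  expect_lt(abs(mean(xpa) - 1 / (1 - exp(-1))), 0.03)
  # counting model hits its target mean
  cfgc <- sim_config(m, model = "counting", m = 4, target_mean = 1.5,
                     seed = 1)
  xc <- draw_exchange_count(cfgc, 2e4)
  expect_lt(abs(mean(xc) - 1.5), 0.05)
  # and is under-dispersed relative to Poisson
  expect_lt(var(xc) / mean(xc), 0.75)
})

test_that("exchange placement follows the intensity profile", {
  m <- map6()
  cfg <- sim_config(m, model = "explicit", E = c(0, 1),
                    intensity = c(1, 0, 0, 0, 0), seed = 2)
  pos <- place_exchanges(cfg, rep(1L, 500))
  expect_true(all(unlist(pos) == 1L))
  cfgu <- sim_config(m, model = "explicit", E = c(0, 1), seed = 2)
  set.seed(8)
  posu <- unlist(place_exchanges(cfgu, rep(1L, 1e5)))
  shares <- tabulate(posu, 5) / 1e5
  expect_true(all(abs(shares - 0.2) < 3 * sqrt(0.2 * 0.8 / 1e5) + 1e-3))
})

test_that("genotype emission flips phase on odd hit counts only", {
  m <- map6()
  g0 <- emit_genotype(integer(0), m)
  expect_identical(as.character(g0), rep("M", 6))
  g1 <- emit_genotype(2L, m)
  expect_identical(as.character(g1), c("M", "M", "W", "W", "W", "W"))
  g2 <- emit_genotype(c(3L, 3L), m)
  expect_identical(as.character(g2), rep("M", 6))
  expect_identical(attr(g2, "hidden_dco"), 1L)
  g3 <- emit_genotype(c(1L, 3L, 3L, 5L), m)
  expect_identical(as.character(g3), c("M", "W", "W", "W", "W", "M"))
})

test_that("truth log accounts for hidden doubles", {
  cfg <- sim_config(map6(), n_crosses = 3, progeny_per_cross = 300,
                    model = "poisson", lambda = 2.5, seed = 31)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth
  n_carried <- lengths(strsplit(tr$chromatid_hits, ","))
  n_carried[tr$chromatid_hits == ""] <- 0L
  expect_true(all(tr$n_observed <= n_carried))
  expect_true(all(n_carried <= tr$n_exchanges))
  no_hidden <- tr$hidden_dco == 0L
  expect_identical(tr$n_observed[no_hidden], n_carried[no_hidden])
  expect_true(any(tr$hidden_dco > 0L))  # lambda high enough to collide
})

test_that("class II exchanges on a single-exchange base are uniform", {
  # emulates a mei-MCM hypomorph: obligate pathway off, residual
  # non-interfering exchanges only
  cfg <- sim_config(map6(), n_crosses = 4, progeny_per_cross = 5000,
                    model = "explicit", E = c(1, 0),
                    intensity = c(0, 0, 1, 0, 0),  # must be ignored by class II
                    class2_rate = 0.3, seed = 53)
  sim <- simulate_experiment(cfg)
  tab <- pool_crosses(sim$collection)
  counts <- tab$interval_counts
  r <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  expect_gt(r$p.value, 0.001)
  expect_true(all(sim$truth$n_class2 == sim$truth$n_exchanges))
})

test_that("Weinstein inversion recovers the generating distribution", {
  E <- reference_tetrads()$pse
  cfg <- sim_config(map6(), n_crosses = 14, progeny_per_cross = 100,
                    model = "explicit", E = E,
                    intensity = reference_intensity()$pse, seed = 77)
  sim <- simulate_experiment(cfg)
  tab <- pool_crosses(sim$collection)
  td <- suppressWarnings(weinstein_invert(tab$class_counts / tab$n_progeny))
  n <- tab$n_progeny
  # delta-method SE of each inverted class: E_hat_n = c_n . a_hat with
  # multinomial a_hat, so var = (sum c^2 a - E_n^2) / n
  Cmat <- solve(meiocross:::weinstein_matrix(3))
  a <- forward_gamete_distribution(E)
  for (j in 1:4) {
    se <- sqrt((sum(Cmat[j, ]^2 * a) - E[j]^2) / n)
    expect_lt(abs(td$E[j] - E[j]), 3 * se)
  }
  # moments land near the generating values
  expect_equal(td$mean, tetrad_moments(E)[["mean"]], tolerance = 0.1)
})
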