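test_that("interval merging is parity-aware, matching the endpoint oracle", {
  m <- map6()
  G <- all_genotypes_k(6L)
  coll <- coll_of(G, m)
  merged <- merge_intervals(coll, list(c("ho-dp", "dp-b")))
  expect_identical(merged$map$intervals,
                   c("net-ho", "ho-b", "b-pr", "pr-cn"))
  # oracle: indicator = endpoint comparison of ho (col 2) vs b (col 4)
  oracle <- sum(G[, 2] != G[, 4])
  expect_identical(unname(merged$tab$interval_counts[["ho-b"]]),
                   as.integer(oracle))
  # per-progeny parity: double crossover inside the merge scores 0
  dco <- c("M", "M", "W", "M", "M", "M")  # switches ho-dp and dp-b
  sub <- merge_intervals(coll_of(rbind(dco), m), list(c("ho-dp", "dp-b")))
  expect_identical(unname(sub$tab$interval_counts[["ho-b"]]), 0L)
  sco <- c("M", "M", "W", "W", "W", "W")
  sub2 <- merge_intervals(coll_of(rbind(sco), m), list(c("ho-dp", "dp-b")))
  expect_identical(unname(sub2$tab$interval_counts[["ho-b"]]), 1L)
  # idempotent: merging an already-single interval changes nothing
  again <- merge_intervals(merged$coll, list("ho-b"))
  expect_identical(again$tab$interval_counts, merged$tab$interval_counts)
  expect_error(merge_intervals(coll, list(c("net-ho", "dp-b"))),
               "contiguous")
})

test_that("coincidence arithmetic follows obs/(n f1 f2)", {
  m <- map6()
  # 100 progeny: 1 double (net-ho & ho-dp), 19 only net-ho, 9 only ho-dp
  g_both <- c("M", "W", "M", "M", "M", "M")
  g_a <- c("M", "W", "W", "W", "W", "W")
  g_b <- c("M", "M", "W", "W", "W", "W")
  geno <- do.call(rbind, c(list(g_both), rep(list(g_a), 19),
                           rep(list(g_b), 9), rep(list(rep("M", 6)), 71)))
  r <- coincidence_for_pair(coll_of(geno, m), "net-ho", "ho-dp")
  expect_equal(r$f1, 0.2)
  expect_equal(r$f2, 0.1)
  expect_equal(r$obs_dco, 1)
  expect_equal(r$exp_dco, 2)
  expect_equal(r$coincidence, 0.5)
  expect_equal(r$I, 0.5)
  # complete interference: no doubles at all
  geno0 <- geno[-1, , drop = FALSE]
  r0 <- coincidence_for_pair(coll_of(geno0, m), "net-ho", "ho-dp")
  expect_equal(r0$obs_dco, 0)
  expect_equal(r0$I, 1)
  # obs == exp -> I = 0: 4 doubles, f1 = f2 = 0.2, n = 100
  geno1 <- do.call(rbind, c(rep(list(g_both), 4), rep(list(g_a), 16),
                            rep(list(g_b), 16), rep(list(rep("M", 6)), 64)))
  expect_equal(coincidence_for_pair(coll_of(geno1, m),
                                    "net-ho", "ho-dp")$I, 0)
  # zero frequency -> undefined
  r_na <- coincidence_for_pair(coll_of(geno0[20:28, , drop = FALSE], m),
                               "net-ho", "ho-dp")
  expect_true(is.na(r_na$I))
  expect_error(coincidence_for_pair(coll_of(geno, m),
                                    c("net-ho", "ho-dp"), "ho-dp"),
               "disjoint")
})

test_that("per-cross interference feeds the Mann-Whitney comparison", {
  cfg <- sim_config(map6(), n_crosses = 6, progeny_per_cross = 120,
                    model = "explicit", E = c(0.1, 0.4, 0.4, 0.1),
                    seed = 3)
  coll <- simulate_experiment(cfg)$collection
  per <- interference_by_cross(coll, c("ho-dp", "dp-b"), "b-pr")
  expect_identical(nrow(per), 6L)
  # each row agrees with a direct single-cross computation
  one <- coll
  one$crosses <- coll$crosses["cross03"]
  direct <- coincidence_for_pair(one, c("ho-dp", "dp-b"), "b-pr")
  expect_equal(per$I[per$cross_id == "cross03"], direct$I)
  # identical groups compare as indistinguishable
  r <- compare_interference(coll, coll, c("ho-dp", "dp-b"), "b-pr")
  expect_equal(r$p, 1)
  expect_identical(r$n_used, c(6L, 6L))
  # too few usable crosses errors
  two <- coll
  two$crosses <- coll$crosses[1]
  expect_error(compare_interference(two, coll, c("ho-dp", "dp-b"), "b-pr"),
               ">= 2 crosses")
})

test_that("independent placement gives coincidence near 1, counting model gives I > 0", {
  # no-interference model: exchanges placed independently
  cfg0 <- sim_config(map6(), n_crosses = 4, progeny_per_cross = 2500,
                     model = "poisson", lambda = 1.6, seed = 47)
  coll0 <- simulate_experiment(cfg0)$collection
  r0 <- coincidence_for_pair(coll0, c("ho-dp", "dp-b"), "b-pr")
  se <- 1 / sqrt(r0$exp_dco)
  expect_lt(abs(r0$coincidence - 1), 4 * se)
  # counting-model interference m = 4: strong positive interference
  cfg1 <- sim_config(map6(), n_crosses = 4, progeny_per_cross = 2500,
                     model = "counting", m = 4, target_mean = 1.6, seed = 47)
  coll1 <- simulate_experiment(cfg1)$collection
  r1 <- coincidence_for_pair(coll1, c("ho-dp", "dp-b"), "b-pr")
  expect_gt(r1$I, 0.2)
})
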