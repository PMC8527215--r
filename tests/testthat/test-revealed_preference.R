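# GARP relations, CCEI and the auxiliary consistency indices, checked
# against hand-derived values on the crossing fixture and brute-force
# oracles on random instances.

test_that("cost matrix holds budgets on the diagonal and cross costs off it", {
  obs <- two_obs_fixture()
  C <- cost_matrix(obs)
  expect_equal(diag(C), c(100, 100))
  expect_equal(C[1, 2], 100 / 3)
  expect_equal(C[2, 1], 100 / 3)
  one <- observation_set(x = rbind(c(50, 25)), p = rbind(c(1, 2)))
  expect_equal(cost_matrix(one), matrix(100, 1, 1))
})

test_that("relations shrink with efficiency and exclude identical bundles", {
  obs <- two_obs_fixture()
  r1 <- relations_at_efficiency(obs, 1)
  expect_true(all(r1$RD[1, 2], r1$RD[2, 1], r1$PD[1, 2], r1$PD[2, 1]))
  r0 <- relations_at_efficiency(obs, 0)
  expect_false(any(r0$RD))
  # identical chosen bundles are not mutually revealed preferred
  same <- observation_set(x = rbind(c(50, 50), c(50, 50)),
                          p = rbind(c(1, 1), c(1, 1)))
  expect_false(any(relations_at_efficiency(same, 1)$RD))
  expect_error(relations_at_efficiency(obs, 1.2), "\\[0, 1\\]")
})

test_that("the crossing fixture yields the derived index values", {
  obs <- two_obs_fixture()
  v <- garp_violations(obs)
  expect_equal(nrow(v), 2)
  expect_setequal(paste(v[, "i"], v[, "j"]), c("1 2", "2 1"))
  expect_equal(ccei_breakpoint(obs), 1 / 3)
  expect_equal(ccei(obs), 1 / 3, tolerance = 1e-5)
  expect_equal(count_inconsistent_choices(obs), 2)
  hm <- houtman_maks(obs)
  expect_equal(hm$removed, 1)
  expect_equal(hm$fraction, 0.5)
  expect_true(hm$exact)
  expect_equal(money_pump_index(obs), 2 / 3)
  mc <- minimum_cost_index(obs)
  expect_equal(mc$mci, 1 / 3)
  expect_true(mc$exact)
})

test_that("single observations and consistent data are trivially clean", {
  one <- observation_set(x = rbind(c(10, 45)), p = rbind(c(1, 2)))
  expect_equal(nrow(garp_violations(one)), 0)
  expect_equal(ccei(one), 1)
  b <- simulate_chooser_block(chooser_spec("linear-utility", w = 0.7), seed = 3)
  rep <- consistency_report(b)
  expect_equal(rep$ccei, 1)
  expect_equal(rep$n_violating_pairs, 0)
  expect_equal(rep$hmi_removed, 0)
  expect_equal(rep$mpi, 0)
  expect_equal(rep$mci, 0)
})

test_that("bisection CCEI matches breakpoint enumeration on random instances", {
  set.seed(11)
  for (i in 1:60) {
    obs <- random_obs(n = 8)
    expect_lte(abs(ccei(obs) - ccei_breakpoint(obs)), 2e-6)
  }
})

test_that("violating pairs are monotone in efficiency (binary search is valid)", {
  set.seed(13)
  for (i in 1:20) {
    obs <- random_obs(n = 10)
    es <- sort(runif(4))
    pairs_at <- lapply(es, function(e) {
      v <- garp_violations(obs, e)
      paste(v[, 1], v[, 2])
    })
    for (k in seq_len(3)) {
      expect_true(all(pairs_at[[k]] %in% pairs_at[[k + 1]]))
    }
  }
})

test_that("Houtman-Maks exact search matches full subset brute force", {
  set.seed(17)
  for (i in 1:25) {
    obs <- random_obs(n = sample(4:8, 1))
    expect_equal(houtman_maks(obs)$removed, hmi_brute_force(obs))
  }
})

test_that("greedy fallbacks never beat the exact optima", {
  set.seed(19)
  for (i in 1:15) {
    obs <- random_obs(n = 7)
    exact <- houtman_maks(obs)
    greedy <- houtman_maks(obs, node_budget = 0)
    expect_gte(greedy$removed, exact$removed)
    expect_false(nrow(garp_violations(obs)) > 0 && greedy$exact)
    mex <- minimum_cost_index(obs)
    mgr <- minimum_cost_index(obs, max_exact_edges = -1)
    expect_gte(mgr$mci + 1e-12, mex$mci)
  }
})

test_that("money pump costs are means over violating cycles, within [0, 1]", {
  set.seed(23)
  for (i in 1:20) {
    obs <- random_obs(n = 8)
    mpi <- money_pump_index(obs)
    expect_gte(mpi, 0)
    expect_lte(mpi, 1)
    if (nrow(garp_violations(obs)) == 0) expect_equal(mpi, 0)
  }
  # longer cycle caps can only add cycles, never invalidate the value
  obs <- two_obs_fixture()
  expect_equal(money_pump_index(obs, max_cycle_len = 5), 2 / 3)
})

test_that("indices are invariant to reordering and joint price-budget rescaling", {
  set.seed(29)
  obs <- random_obs(n = 8)
  perm <- sample(obs$n)
  obs_p <- observation_set(obs$x[perm, ], obs$p[perm, ], obs$m[perm])
  scale <- runif(obs$n, 0.5, 4)
  obs_s <- observation_set(obs$x, obs$p * scale, obs$m * scale)
  for (o2 in list(obs_p, obs_s)) {
    expect_equal(ccei_breakpoint(obs), ccei_breakpoint(o2))
    expect_equal(count_inconsistent_choices(obs), count_inconsistent_choices(o2))
    expect_equal(houtman_maks(obs)$removed, houtman_maks(o2)$removed)
    expect_equal(money_pump_index(obs), money_pump_index(o2))
    expect_equal(minimum_cost_index(obs)$mci, minimum_cost_index(o2)$mci)
  }
})

test_that("the literal single-sided relaxation is at most the canonical CCEI", {
  set.seed(31)
  for (i in 1:20) {
    obs <- random_obs(n = 8)
    expect_lte(ccei_breakpoint(obs, literal = TRUE),
               ccei_breakpoint(obs) + 1e-12)
  }
})

test_that("blocks without recorded choices are rejected", {
  b <- generate_block("p1", t = 1, seed = 1)
  expect_error(block_observations(b), "choice_index")
  expect_error(consistency_report(b), "choice_index")
})
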