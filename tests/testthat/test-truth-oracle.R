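test_that("enumeration reproduces hand-computed trajectory sums", {
  # treatment forced on/off via degenerate treatment tables; the expected
  # values below were computed by hand from the default conditional tables
  # (two-year trajectory sums over L1, L2)
  always <- tiny_dgp_config(tau = 2, p_A = rep(list(matrix(1, 2, 2)), 2))
  never <- tiny_dgp_config(tau = 2, p_A = rep(list(matrix(0, 2, 2)), 2))
  expect_equal(truth_by_enumeration(always, policy_spec("identity"), 2)$value,
               0.24792, tolerance = 1e-10)
  expect_equal(truth_by_enumeration(never, policy_spec("identity"), 2)$value,
               0.36725, tolerance = 1e-10)
})

test_that("outcome independent of treatment gives the same value under every policy", {
  cfg <- tiny_dgp_config(tau = 1, p_Y = list(matrix(0.3, 2, 2)))
  vals <- vapply(c("identity", "scenario1", "scenario2", "scenario3"),
                 function(id) {
                   truth_by_enumeration(cfg, policy_spec(id, rng_seed = 1), 1)$value
                 }, 0)
  expect_equal(unname(vals), rep(0.3, 4), tolerance = 1e-12)
})

test_that("identity enumeration equals a direct observed-law computation", {
  cfg <- tiny_dgp_config(tau = 2)
  # independent direct sum over (L1, A1, L2, A2)
  direct <- 0
  for (l1 in 0:1) for (a1 in 0:1) for (l2 in 0:1) for (a2 in 0:1) {
    pl1 <- if (l1 == 1) cfg$p_L1 else 1 - cfg$p_L1
    pa1 <- cfg$p_A[[1]][l1 + 1, 1]; pa1 <- if (a1 == 1) pa1 else 1 - pa1
    pl2 <- cfg$p_L[[2]][l1 + 1, a1 + 1]; pl2 <- if (l2 == 1) pl2 else 1 - pl2
    pa2 <- cfg$p_A[[2]][l2 + 1, a1 + 1]; pa2 <- if (a2 == 1) pa2 else 1 - pa2
    h1 <- cfg$p_Y[[1]][l1 + 1, a1 + 1]
    h2 <- cfg$p_Y[[2]][l2 + 1, a2 + 1]
    direct <- direct + pl1 * pa1 * pl2 * pa2 * (1 - (1 - h1) * (1 - h2))
  }
  expect_equal(truth_by_enumeration(cfg, policy_spec("identity"), 2)$value,
               direct, tolerance = 1e-12)
})

test_that("enumeration is invariant to the order of trajectory summation", {
  cfg <- tiny_dgp_config(tau = 2)
  tr <- truth_by_enumeration(cfg, policy_spec("scenario3", rng_seed = 1), 2)
  paths <- tr$paths
  set.seed(1)
  for (i in 1:5) {
    perm <- sample(nrow(paths))
    expect_equal(1 - sum(paths$prob[perm] * paths$surv[perm]), tr$value,
                 tolerance = 1e-12)
  }
  expect_equal(sum(paths$prob), 1, tolerance = 1e-12)
})

test_that("simulation truth matches enumeration within monte-carlo error", {
  cfg <- tiny_dgp_config(tau = 2)
  for (id in c("identity", "scenario1", "scenario3")) {
    sp <- policy_spec(id, rng_seed = 3)
    en <- truth_by_enumeration(cfg, sp, 2)
    si <- truth_by_simulation(cfg, sp, 2, n_mc = 150000, seed = 5)
    expect_lt(abs(si$value - en$value), 3 * si$mc_se)
  }
})

test_that("monte-carlo standard error halves when n is quadrupled", {
  cfg <- tiny_dgp_config(tau = 2)
  s1 <- truth_by_simulation(cfg, policy_spec("identity"), 2,
                            n_mc = 20000, seed = 1)
  s2 <- truth_by_simulation(cfg, policy_spec("identity"), 2,
                            n_mc = 80000, seed = 1)
  expect_equal(s1$mc_se / s2$mc_se, 2, tolerance = 0.2)
})

test_that("a protective treatment orders the policies: more care, fewer events", {
  cfg <- tiny_dgp_config(tau = 2)   # default hazard tables are protective
  v <- vapply(c("scenario1", "identity", "scenario3"), function(id) {
    truth_by_enumeration(cfg, policy_spec(id, rng_seed = 2), 2)$value
  }, 0)
  expect_gt(v["scenario1"], v["identity"])   # restriction raises incidence
  expect_gt(v["identity"], v["scenario3"])   # extension lowers it
})

test_that("horizon and capacity violations raise errors", {
  cfg <- tiny_dgp_config(tau = 2)
  expect_error(truth_by_enumeration(cfg, policy_spec("identity"), 3), "horizon")
  expect_error(truth_by_simulation(cfg, policy_spec("identity"), 5, 100, 1),
               "horizon")
  expect_error(tiny_dgp_config(tau = 2, p_Y = list(matrix(1.2, 2, 2),
                                                   matrix(0.1, 2, 2))),
               "p_Y")
})
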