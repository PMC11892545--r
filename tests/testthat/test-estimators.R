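test_that("identity policy on a censoring-free panel recovers the empirical incidence", {
  cfg <- dgp_config(n_persons = 3000, n_years = 4)
  panel <- simulate_cohort(cfg, seed = 21, censoring = FALSE)
  emp <- mean(panel$Y_2013)
  prep <- periopolicy:::lmtp_prep(panel, fast_control(), seed = 22)
  sdr <- estimate_sdr(prep, policy_spec("identity"), 2)
  expect_lt(abs(sdr$psi - emp), 2 * sdr$se)
  # the IPW cross-check is exact here: all ratios and factors are 1
  ipw <- estimate_ipw(prep, policy_spec("identity"), 2)
  expect_equal(ipw$psi, emp, tolerance = 1e-12)
})

test_that("saturated g-computation without cross-fitting is the empirical mean", {
  cfg <- tiny_dgp_config(tau = 2)
  d <- periopolicy:::simulate_tiny(cfg, 4000, seed = 23)
  ctl <- sat_control(cf_folds = 1)
  g <- estimate_gcomp(d, policy_spec("identity"), 2, ctl, seed = 24)
  expect_equal(g$psi, mean(d$Y[, 3]), tolerance = 1e-10)
  expect_true(is.na(g$se))                      # point cross-check only
})

test_that("estimates are probabilities with coherent intervals", {
  cfg <- tiny_dgp_config(tau = 2)
  d <- periopolicy:::simulate_tiny(cfg, 1500, seed = 25)
  for (id in c("identity", "scenario1", "scenario3")) {
    e <- estimate_sdr(d, policy_spec(id, rng_seed = 1), 2, sat_control(),
                      seed = 26)
    expect_gte(e$psi, 0); expect_lte(e$psi, 1)
    expect_gte(e$psi, e$ci[1]); expect_lte(e$psi, e$ci[2])
    expect_gt(e$se, 0)
    g <- estimate_gcomp(d, policy_spec(id, rng_seed = 1), 2, sat_control(),
                        seed = 26)
    expect_gte(g$psi, 0); expect_lte(g$psi, 1)
    i <- estimate_ipw(d, policy_spec(id, rng_seed = 1), 2, sat_control(),
                      seed = 26)
    expect_gte(i$psi, 0)
  }
  expect_error(estimate_sdr(d, policy_spec("identity"), 5, sat_control()),
               "horizon")
})

test_that("policies identical by construction give identical estimates", {
  # a cohort whose treated years are all subgingival: the supragingival
  # restriction has nothing to alter, so it must equal the identity fit
  cfg <- dgp_config(n_persons = 800, n_years = 4,
                    treatment_model = list(sub = list(intercept = 30,
                                                      b_propensity = 0)))
  panel <- simulate_cohort(cfg, seed = 27)
  expect_true(all(treatment_matrix(panel) %in% c("NONE", "SUB", NA)))
  prep <- periopolicy:::lmtp_prep(panel, fast_control(), seed = 28)
  a <- estimate_sdr(prep, policy_spec("scenario2"), 3)
  b <- estimate_sdr(prep, policy_spec("identity"), 3)
  expect_identical(a$psi, b$psi)
  expect_identical(a$scores, b$scores)
})

test_that("estimator trio converges to the enumerated truth on the tiny process", {
  cfg <- tiny_dgp_config(tau = 2)
  d <- periopolicy:::simulate_tiny(cfg, 50000, seed = 29)
  prep <- periopolicy:::lmtp_prep(d, sat_control(), seed = 30)
  for (id in c("identity", "scenario1")) {
    sp <- policy_spec(id)
    truth <- truth_by_enumeration(cfg, sp, 2)$value
    vals <- c(sdr = estimate_sdr(prep, sp, 2)$psi,
              gcomp = estimate_gcomp(prep, sp, 2)$psi,
              ipw = estimate_ipw(prep, sp, 2)$psi)
    expect_lt(max(abs(vals - truth)), 0.01)
    expect_lt(diff(range(vals)), 0.02)          # estimator spread
  }
})

test_that("contrasts do paired-score inference and exact self-comparison", {
  cfg <- tiny_dgp_config(tau = 2)
  d <- periopolicy:::simulate_tiny(cfg, 2000, seed = 31)
  prep <- periopolicy:::lmtp_prep(d, sat_control(), seed = 32)
  a <- estimate_sdr(prep, policy_spec("scenario1"), 2)
  b <- estimate_sdr(prep, policy_spec("identity"), 2)
  ct <- contrast(a, b)
  expect_equal(ct$rd, a$psi - b$psi)
  expect_gte(ct$rd, -1); expect_lte(ct$rd, 1)
  expect_gt(ct$rr, 0)
  expect_true(ct$rd_low <= ct$rd && ct$rd <= ct$rd_high)

  self <- contrast(a, a)
  expect_identical(self$rd, 0)
  expect_identical(self$rr, 1)
  expect_identical(self$rd_se, 0)

  # hand arithmetic on synthetic estimate objects
  mk <- function(psi, scores) {
    structure(list(psi = psi, scores = scores, horizon = 1L, policy = "x",
                   estimator = "sdr"), class = "lmtp_estimate")
  }
  h <- contrast(mk(0.25, rep(0.25, 100)), mk(0.20, rep(0.20, 100)))
  expect_equal(h$rd, 0.05)
  expect_equal(h$rr, 1.25)

  a1 <- estimate_sdr(prep, policy_spec("scenario1"), 1)
  expect_error(contrast(a1, b), "horizon")
})

test_that("a protective effect shows up with the oracle's sign", {
  cfg <- dgp_config(n_persons = 20000, n_years = 6,
                    outcome_model = list(theta_treat = -0.3))
  truth_id <- truth_by_simulation(cfg, policy_spec("identity"), 5,
                                  n_mc = 150000, seed = 33)
  truth_s1 <- truth_by_simulation(cfg, policy_spec("scenario1"), 5,
                                  n_mc = 150000, seed = 34)
  expect_lt(truth_id$value, truth_s1$value)    # more care, fewer extractions
  panel <- simulate_cohort(cfg, seed = 35)
  prep <- periopolicy:::lmtp_prep(panel, fast_control(), seed = 36)
  ct <- contrast(estimate_sdr(prep, policy_spec("identity"), 5),
                 estimate_sdr(prep, policy_spec("scenario1"), 5))
  expect_lt(ct$rd, 0)                          # resolvable at n = 20 000
  expect_lt(ct$rd_high, 0)
})
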