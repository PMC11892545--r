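test_that("identity policy yields unit ratios and unit censoring-free factors", {
  cfg <- tiny_dgp_config(tau = 2)
  d <- periopolicy:::simulate_tiny(cfg, 600, seed = 2)
  r <- estimate_density_ratios(d, policy_spec("identity"), sat_control(),
                               seed = 3)
  expect_true(all(r$r_cls[!is.na(r$r_cls)] == 1))
  expect_true(all(r$censor_factor[!is.na(r$censor_factor)] == 1))
  expect_true(any(grepl("ratios set to 1", r$notes)))
  expect_true(all(r$r[!is.na(r$r)] >= 0))
})

test_that("saturated classifier recovers the analytic density ratio", {
  cfg <- tiny_dgp_config(tau = 2)
  d <- periopolicy:::simulate_tiny(cfg, 50000, seed = 7)
  # single estimation fold: the check is against the analytic ratio, and
  # full-sample cell frequencies keep the comparison within binomial noise
  ctl <- sat_control(stabilize_ratios = FALSE, cf_folds = 1)
  r <- estimate_density_ratios(d, policy_spec("scenario1"), ctl, seed = 8)
  A <- d$X == "SUB"
  L2 <- d$L[[2]]$L
  # analytic ratio at year 2 under the consecutive-care ban:
  #   prev untreated: policy keeps the natural draw, ratio 1
  #   prev treated, natural treated: assigned density is zero, ratio 0
  #   prev treated, natural untreated: all policy mass lands on NONE, 1/g(NONE)
  g1 <- cfg$p_A[[2]][cbind(L2 + 1, 2)]      # P(A2 = 1 | L2, A1 = 1)
  expected <- ifelse(!A[, 1], 1, ifelse(A[, 2], 0, 1 / (1 - g1)))
  ok <- !is.na(r$r_cls[, 2])                # off the at-risk set: no ratio
  expect_lt(max(abs(r$r_cls[ok, 2] - expected[ok])), 0.05)
  expect_true(all(abs(r$r_cls[, 1] - 1) < 1e-9))  # first year always kept
})

test_that("ratio stabilization rescales each year to mean one", {
  cfg <- tiny_dgp_config(tau = 2)
  d <- periopolicy:::simulate_tiny(cfg, 20000, seed = 9)
  r <- estimate_density_ratios(d, policy_spec("scenario1"), sat_control(),
                               seed = 10)
  expect_equal(mean(r$r_cls[, 2], na.rm = TRUE), 1, tolerance = 1e-9)
})

test_that("censoring model is calibrated against the generator's true hazard", {
  cfg <- dgp_config(n_persons = 20000, n_years = 4)
  panel <- simulate_cohort(cfg, seed = 13, keep_truth = TRUE)
  true_p <- attr(panel, "true_obs_prob")
  pC <- fit_censoring_model(panel, fast_control(), seed = 14)
  obs <- panel$O_2011 == 1
  fit <- stats::lm(true_p[obs, 1] ~ pC[obs, 1])
  slope <- unname(stats::coef(fit)[2])
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
  expect_true(all(pC >= 0.01, na.rm = TRUE))   # floor bounds factors by 100
})

test_that("censoring-free panels give inert censoring factors", {
  cfg <- dgp_config(n_persons = 500, n_years = 4)
  panel <- simulate_cohort(cfg, seed = 4, censoring = FALSE)
  pC <- fit_censoring_model(panel, fast_control(), seed = 5)
  expect_true(all(pC == 1))
})

test_that("positivity diagnostics summarise cumulative weights per horizon", {
  cfg <- tiny_dgp_config(tau = 2)
  d <- periopolicy:::simulate_tiny(cfg, 2000, seed = 11)
  r_id <- estimate_density_ratios(d, policy_spec("identity"), sat_control(),
                                  seed = 12)
  pos <- positivity_diagnostics(r_id)
  expect_equal(nrow(pos), 2)                       # one row per horizon
  expect_equal(pos$max_weight, c(1, 1), tolerance = 1e-9)

  # forcing near-universal extension on a rarely treated process is flagged
  rare <- tiny_dgp_config(tau = 2, p_A = rep(list(matrix(0.05, 2, 2)), 2))
  dr <- periopolicy:::simulate_tiny(rare, 4000, seed = 13)
  ctl <- sat_control(positivity_bound = 5)
  est <- estimate_sdr(dr, policy_spec("scenario3", mix_probability = 1,
                                      rng_seed = 14), 2, ctl, seed = 15)
  expect_true(length(est$warnings) > 0)
  expect_match(est$warnings[1], "positivity")
  expect_true(is.finite(est$psi))                  # estimation proceeds
})
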