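test_that("simulation is deterministic and the empty cohort keeps the schema", {
  cfg <- dgp_config(n_persons = 200, n_years = 4)
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(cfg, seed = 6)))

  e <- simulate_cohort(dgp_config(n_persons = 0, n_years = 4), seed = 1)
  expect_equal(nrow(e), 0)
  expect_true(all(c("sex", "hist_years_supra", "L_income_2011", "X_2011",
                    "W_exam_2013", "O_2014", "Y_2014") %in% names(e)))
  s <- summarize_cohort(e)
  expect_true(s$undefined)
  expect_true(is.nan(s$cumulative_incidence))
})

test_that("configuration errors name the offending field", {
  expect_error(dgp_config(baseline_dists = list(education = c(a = 0.4, b = 0.4))),
               "education")
  expect_error(dgp_config(n_years = 1), "n_years")
  expect_error(dgp_config(outcome_model = list(intercept = NaN)), "outcome_model")
  expect_error(dgp_config(history_dists = list(q_sub = c(-1, 2))), "q_sub")
})

test_that("panel flags are monotone and diabetes is absorbing", {
  p <- small_panel()
  O <- as.matrix(p[grep("^O_", names(p))])
  expect_true(all(apply(O, 1, function(o) all(diff(o) <= 0))))
  Y <- as.matrix(p[grep("^Y_", names(p))])
  expect_true(all(apply(Y, 1, function(y) {
    y <- y[!is.na(y)]; length(y) < 2 || all(diff(y) >= 0)
  })))
  D <- as.matrix(p[grep("^L_diabetes_", names(p))])
  expect_true(all(apply(D, 1, function(d) {
    d <- d[!is.na(d)]; length(d) < 2 || all(diff(d) >= 0)
  })))
})

test_that("monte-carlo error of a marginal scales as one over root n", {
  frac_male <- function(n, seed) {
    mean(simulate_cohort(dgp_config(n_persons = n, n_years = 2),
                         seed = seed)$sex == "male")
  }
  se_at <- function(n) stats::sd(vapply(1:30, function(s) frac_male(n, s), 0))
  r <- se_at(400) / se_at(1600)
  expect_gt(r, 2 * 0.8)   # within 20% of the root-n factor 2
  expect_lt(r, 2 * 1.25)
})

test_that("censoring is informative by construction", {
  p <- default_panel()
  lost <- p$O_2021 == 0
  # diabetes and low income both raise the loss hazard
  expect_gt(mean(p$L_diabetes_2011[lost]), mean(p$L_diabetes_2011[!lost]))
  expect_lt(mean(p$L_income_2011[lost]), mean(p$L_income_2011[!lost]))
  expect_gt(abs(stats::cor(p$L_income_2011, as.numeric(lost))), 0.01)
})

test_that("with a null treatment effect the generator is policy-invariant", {
  cfg <- dgp_config(n_persons = 30000, n_years = 6)  # theta_treat = 0 default
  k <- 5
  t_id <- truth_by_simulation(cfg, policy_spec("identity"), k,
                              n_mc = 30000, seed = 21)
  for (id in c("scenario1", "scenario3")) {
    t_pol <- truth_by_simulation(cfg, policy_spec(id, rng_seed = 3), k,
                                 n_mc = 30000, seed = 22)
    tol <- 3 * sqrt(t_id$mc_se^2 + t_pol$mc_se^2)
    expect_lt(abs(t_pol$value - t_id$value), tol)
  }
})

test_that("a nonzero unobserved confounding dial changes both processes", {
  cfg0 <- dgp_config(n_persons = 5000, n_years = 3)
  cfg1 <- dgp_config(n_persons = 5000, n_years = 3, confounding_dial = 1.5)
  p0 <- simulate_cohort(cfg0, seed = 8, censoring = FALSE)
  p1 <- simulate_cohort(cfg1, seed = 8, censoring = FALSE)
  # frailty inflates the association between treatment and next-year outcome
  or_ <- function(p) {
    tr <- p$X_2011 != "NONE"
    (mean(p$Y_2012[tr]) / (1 - mean(p$Y_2012[tr]))) /
      (mean(p$Y_2012[!tr]) / (1 - mean(p$Y_2012[!tr])))
  }
  expect_gt(or_(p1), or_(p0) * 1.3)
})

test_that("cohort summaries are computed among the observed", {
  s <- summarize_cohort(default_panel())
  expect_equal(s$yearly$n_observed[1], 20000)
  expect_lt(s$yearly$n_observed[10], 20000)
  expect_true(all(s$yearly$diabetes >= 0 & s$yearly$diabetes <= 1, na.rm = TRUE))
  # mean treated years on a hand-built 2-person panel: one always, one never
  hp <- hand_panel(tau = 4)
  sh <- summarize_cohort(hp)
  expect_equal(sh$therapy_years_mean, 2)   # tau / 2
  expect_output(print(s), "cumulative incidence")
})
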