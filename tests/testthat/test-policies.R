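test_that("scenario rules transform hand histories exactly as specified", {
  # restriction of any care in consecutive years, applied left to right
  expect_equal(apply_policy(c("SUB", "SUB", "NONE", "SUPRA"),
                            policy_spec("scenario1")),
               c("SUB", "NONE", "NONE", "SUPRA"))
  # supragingival-only restriction never touches SUB years
  expect_equal(apply_policy(c("SUPRA", "SUPRA", "SUB", "SUB", "SUPRA"),
                            policy_spec("scenario2")),
               c("SUPRA", "NONE", "SUB", "SUB", "SUPRA"))
  # extension policy with degenerate randomisation: the third year's
  # predecessor in the natural history is NONE, so it stays NONE
  expect_equal(apply_policy(c("SUPRA", "NONE", "NONE"),
                            policy_spec("scenario3", mix_probability = 1,
                                        rng_seed = 1)),
               c("SUPRA", "SUPRA", "NONE"))
  # nothing to restrict or extend
  none <- rep("NONE", 6)
  for (id in c("identity", "scenario1", "scenario2", "scenario3")) {
    expect_equal(apply_policy(none, policy_spec(id, rng_seed = 1)), none)
  }
})

test_that("policy invariants hold on random treatment histories", {
  set.seed(42)
  X <- matrix(sample(treatment_levels(), 500 * 10, TRUE,
                     prob = c(0.4, 0.45, 0.15)), 500, 10)
  s1 <- apply_policy(X, policy_spec("scenario1"))
  s2 <- apply_policy(X, policy_spec("scenario2"))
  s3 <- apply_policy(X, policy_spec("scenario3", rng_seed = 9))

  treated <- function(m) m != "NONE"
  # no two consecutive treated years after scenario 1 (exact)
  expect_false(any(treated(s1)[, -1] & treated(s1)[, -10]))
  # scenario 2: SUB entries identical to input; no consecutive SUPRA
  expect_equal(s2[X == "SUB"], X[X == "SUB"])
  expect_false(any(s2[, -1] == "SUPRA" & s2[, -10] == "SUPRA"))
  # per-person counts ordered: s1 <= observed, s3 >= observed, s2 <= observed
  expect_true(all(rowSums(treated(s1)) <= rowSums(treated(X))))
  expect_true(all(rowSums(treated(s2)) <= rowSums(treated(X))))
  expect_true(all(rowSums(treated(s3)) >= rowSums(treated(X))))
  # cohort means ordered scenario1 <= scenario2 <= observed <= scenario3
  m <- vapply(list(s1, s2, X, s3),
              function(m) person_years_with_therapy(m)$mean, 0)
  expect_true(all(diff(m) >= 0))
  # deterministic policies are idempotent
  expect_equal(apply_policy(s1, policy_spec("scenario1")), s1)
  expect_equal(apply_policy(s2, policy_spec("scenario2")), s2)
  # scenario 3 with zero mix probability is the identity
  expect_equal(apply_policy(X, policy_spec("scenario3", mix_probability = 0,
                                           rng_seed = 1)), X)
})

test_that("scenario 3 alters approximately mix_probability of eligible slots", {
  set.seed(7)
  X <- matrix(sample(c("NONE", "SUPRA", "SUB"), 2000 * 10, TRUE,
                     prob = c(0.5, 0.35, 0.15)), 2000, 10)
  eligible <- X[, -1] == "NONE" & X[, -10] != "NONE"
  for (mix in c(0.3, 0.5)) {
    s3 <- apply_policy(X, policy_spec("scenario3", mix_probability = mix,
                                      rng_seed = 4))
    altered <- (s3 != X)[, -1]
    frac <- sum(altered[eligible]) / sum(eligible)
    se <- sqrt(mix * (1 - mix) / sum(eligible))
    expect_lt(abs(frac - mix), 4 * se)
    expect_false(any(altered[!eligible]))
  }
})

test_that("person-years summaries follow the population-SD convention", {
  allnone <- matrix("NONE", 5, 10)
  expect_equal(person_years_with_therapy(allnone)$mean, 0)
  expect_equal(person_years_with_therapy(allnone)$sd, 0)
  two <- rbind(rep("SUB", 10), rep("NONE", 10))
  py <- person_years_with_therapy(two)
  expect_equal(py$mean, 5)
  expect_equal(py$sd, 5)   # population convention, divisor n
  expect_equal(py$per_person, c(10L, 0L))
})

test_that("policy validation rejects bad inputs", {
  expect_error(apply_policy(c("NONE", "SOMETIMES"), policy_spec("scenario1")),
               "SOMETIMES")
  expect_error(apply_policy(c("SUB", "NONE"), policy_spec("scenario3")),
               "seed")
  expect_error(policy_spec("scenario3", mix_probability = 1.4), "mix_probability")
  expect_error(policy_spec("scenario9"))
})
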