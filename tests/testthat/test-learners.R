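make_xy <- function(n = 300, p = 6, seed = 1, sparse = FALSE) {
  with_seed <- get("with_seed", asNamespace("periopolicy"))
  with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    eta <- if (sparse) 2.5 * x[, 1] - 2 * x[, 2] else rowSums(x) * 0.4
    y <- rbinom(n, 1, plogis(eta))
    list(x = x, y = y)
  })
}

test_that("a single-candidate ensemble is the simplex vertex", {
  d <- make_xy()
  sl <- fit_superlearner(d$x, d$y, "binary", glm_learners(), seed = 2)
  expect_equal(sl$weights, 1)
  p <- predict(sl, d$x)
  expect_true(all(p >= 1e-6 & p <= 1 - 1e-6))
})

test_that("stacking weights lie on the simplex and never lose to the best candidate", {
  d <- make_xy(n = 400)
  learners <- list(learner_spec("ridge"), learner_spec("lasso"),
                   learner_spec("mean"))
  sl <- fit_superlearner(d$x, d$y, "binary", learners, n_folds = 5, seed = 3)
  expect_true(all(sl$weights >= 0))
  expect_equal(sum(sl$weights), 1, tolerance = 1e-9)
  expect_lte(sl$ensemble_cv_risk, min(sl$cv_risk) + 1e-9)
  tab <- superlearner_table(sl)
  expect_equal(nrow(tab), 3)
})

test_that("the lasso candidate dominates on a sparse logistic truth", {
  wins <- 0L
  nrep <- 50L
  for (i in seq_len(nrep)) {
    d <- make_xy(n = 250, p = 20, seed = 100 + i, sparse = TRUE)
    sl <- fit_superlearner(d$x, d$y, "binary",
                           list(learner_spec("ridge"), learner_spec("lasso")),
                           n_folds = 3, seed = 200 + i)
    wins <- wins + (which.max(sl$weights) == 2L)
  }
  expect_gte(wins / nrep, 0.8)
})

test_that("degenerate labels produce a constant model with a note", {
  x <- matrix(rnorm(40), 20, 2)
  sl <- fit_superlearner(x, rep(1, 20), "binary", glm_learners(), seed = 1)
  expect_true(sl$degenerate)
  expect_match(sl$note, "single-class")
  expect_equal(unique(predict(sl, x)), 1, tolerance = 1e-5)  # clipped at 1-1e-6
})

test_that("predictions are the convex combination of candidate predictions", {
  # two constant candidates at 0.2 and 0.6 with equal weight give 0.4
  obj <- structure(list(
    weights = c(0.5, 0.5),
    fits = list(structure(list(constant = 0.2), class = "fit_constant"),
                structure(list(constant = 0.6), class = "fit_constant")),
    task = "continuous", yrange = c(0, 1)), class = "superlearner")
  expect_equal(unname(predict(obj, matrix(0, 3, 2))), rep(0.4, 3))
})

test_that("row permutation with carried folds leaves the weights unchanged", {
  d <- make_xy(n = 300)
  foldid <- rep_len(1:5, 300)
  learners <- list(learner_spec("glm"), learner_spec("ridge", lambda = 0.05))
  a <- fit_superlearner(d$x, d$y, "binary", learners, seed = 4, foldid = foldid)
  perm <- rev(seq_len(300))
  b <- fit_superlearner(d$x[perm, ], d$y[perm], "binary", learners, seed = 4,
                        foldid = foldid[perm])
  expect_equal(a$weights, b$weights, tolerance = 1e-8)
})

test_that("row and label requirements are enforced", {
  d <- make_xy(n = 12)
  expect_error(fit_superlearner(d$x, d$y, "binary", glm_learners(),
                                n_folds = 10, seed = 1), "too few rows")
  expect_error(fit_superlearner(d$x, d$y[1:5], "binary", glm_learners(),
                                seed = 1))
})
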