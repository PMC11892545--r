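#' Specify a candidate learner
#'
#' Candidate families for the super-learner stack:
#' \describe{
#'   \item{`"ridge"`}{ridge-regularised GLM (Gaussian-prior MAP estimate of a
#'     Bayesian GLM; identical point predictions, no sampler), penalty chosen
#'     on an internal grid by the ensemble's own folds.}
#'   \item{`"lasso"`}{L1-penalised GLM, same internal penalty selection.}
#'   \item{`"rf"`}{random forest (ranger).}
#'   \item{`"glm"`}{unpenalised GLM: logistic for binary labels, least squares
#'     for continuous labels in `[0, 1]`.}
#'   \item{`"logit"`}{quasibinomial GLM (logistic mean even for fractional
#'     labels).}
#'   \item{`"sat"`}{saturated cell means: one parameter per distinct feature
#'     row; unseen cells fall back to the overall mean. Intended for small
#'     discrete validation processes.}
#'   \item{`"mean"`}{intercept only.}
#' }
#'
#' @param family One of the family names above.
#' @param id Optional label (defaults to the family name).
#' @param ... Hyperparameters: `lambda` (fixed penalty or grid for
#'   ridge/lasso), `num_trees`, `max_depth`, `min_node_size` (rf).
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(family = c("ridge", "lasso", "rf", "glm", "logit",
                                    "sat", "mean"),
                         id = NULL, ...) {
  family <- match.arg(family)
  hp <- list(...)
  if (!is.null(hp$num_trees) && hp$num_trees < 1) {
    stop_config("num_trees", "must be positive")
  }
  structure(list(family = family, id = id %||% family, hyper = hp),
            class = "learner_spec")
}

#' Default learner sets
#'
#' `default_learners()` is the published nuisance ensemble: Bayesian-style
#' (ridge) GLM, LASSO and random forest. `glm_learners()` is the single
#' unpenalised GLM used for fast, large-scale runs and validation studies.
#'
#' @param num_trees Trees for the random-forest candidate.
#' @return A list of [learner_spec()] objects.
#' @export
default_learners <- function(num_trees = 200) {
  list(learner_spec("ridge"), learner_spec("lasso"),
       learner_spec("rf", num_trees = num_trees))
}

#' @rdname default_learners
#' @export
glm_learners <- function() list(learner_spec("glm"))

# ---- candidate fitting -----------------------------------------------------

fit_learner <- function(spec, x, y, task, seed) {
  if (length(unique(y)) == 1L) {
    return(structure(list(constant = y[1]), class = "fit_constant"))
  }
  # near-degenerate binary labels cannot support a model fit
  if (task == "binary" && min(table(y)) < 3L) {
    return(structure(list(constant = mean(y)), class = "fit_constant"))
  }
  switch(spec$family,
    mean = structure(list(constant = mean(y)), class = "fit_constant"),
    sat = fit_sat(x, y),
    glm = fit_glm(x, y, task, quasibinomial = FALSE),
    logit = fit_glm(x, y, task, quasibinomial = TRUE),
    ridge = fit_glmnet(x, y, task, alpha = 0, spec$hyper, seed),
    lasso = fit_glmnet(x, y, task, alpha = 1, spec$hyper, seed),
    rf = fit_rf(x, y, task, spec$hyper, seed)
  )
}

predict_learner <- function(fit, x) {
  switch(class(fit)[1],
    fit_constant = rep(fit$constant, nrow(x)),
    fit_sat = predict_sat(fit, x),
    fit_glm = predict_glm(fit, x),
    fit_glmnet = as.numeric(stats::predict(fit$model, newx = x,
                                           s = fit$lambda, type = "response")),
    fit_rf = {
      p <- stats::predict(fit$model, data = as.data.frame(x))$predictions
      if (is.matrix(p)) p[, "1"] else p
    },
    stop("unknown learner fit class")
  )
}

sat_key <- function(x) do.call(paste, c(as.data.frame(x), sep = "\r"))

fit_sat <- function(x, y) {
  key <- sat_key(x)
  means <- vapply(split(y, key), mean, 0)
  structure(list(means = means, fallback = mean(y)), class = "fit_sat")
}

predict_sat <- function(fit, x) {
  p <- unname(fit$means[sat_key(x)])
  p[is.na(p)] <- fit$fallback
  as.numeric(p)
}

fit_glm <- function(x, y, task, quasibinomial) {
  xm <- cbind(1, x)
  if (task == "binary" || quasibinomial) {
    # sequential pseudo-outcomes may leave [0,1]; map to the unit interval
    # for the quasibinomial fit and invert the map at prediction time
    lo <- min(y, 0); hi <- max(y, 1)
    ys <- (y - lo) / (hi - lo)
    fam <- if (quasibinomial) stats::quasibinomial() else stats::binomial()
    fit <- suppressWarnings(stats::glm.fit(xm, ys, family = fam))
    structure(list(coef = fit$coefficients, link = "logit",
                   scale = c(lo, hi)), class = "fit_glm")
  } else {
    fit <- stats::lm.fit(xm, y)
    structure(list(coef = fit$coefficients, link = "identity"), class = "fit_glm")
  }
}

predict_glm <- function(fit, x) {
  b <- fit$coef
  b[is.na(b)] <- 0
  eta <- as.numeric(cbind(1, x) %*% b)
  if (fit$link == "logit") {
    s <- fit$scale %||% c(0, 1)
    s[1] + (s[2] - s[1]) * stats::plogis(eta)
  } else eta
}

fit_glmnet <- function(x, y, task, alpha, hyper, seed) {
  fam <- if (task == "binary") "binomial" else "gaussian"
  lam <- hyper$lambda %||% NULL
  if (task == "binary") y <- as.numeric(y)
  if (!is.null(lam) && length(lam) == 1L) {
    # rare binary classes trigger advisory warnings; degenerate cases are
    # already routed to the constant learner upstream
    model <- suppressWarnings(
      glmnet::glmnet(x, y, family = fam, alpha = alpha, lambda = lam))
    return(structure(list(model = model, lambda = lam), class = "fit_glmnet"))
  }
  cv <- with_seed(seed, suppressWarnings(
    glmnet::cv.glmnet(x, y, family = fam, alpha = alpha,
                      nfolds = 5, lambda = lam, nlambda = 30)))
  structure(list(model = cv$glmnet.fit, lambda = cv$lambda.min),
            class = "fit_glmnet")
}

fit_rf <- function(x, y, task, hyper, seed) {
  df <- as.data.frame(x)
  df$.y <- if (task == "binary") factor(y, levels = c(0, 1)) else y
  model <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = hyper$num_trees %||% 200,
    max.depth = hyper$max_depth %||% 0,
    min.node.size = hyper$min_node_size %||% if (task == "binary") 10 else 20,
    probability = task == "binary",
    seed = seed, num.threads = 1
  )
  structure(list(model = model), class = "fit_rf")
}

# ---- super learner ---------------------------------------------------------

#' Fit a super learner (stacked ensemble)
#'
#' V-fold cross-validated stacking: each candidate is fitted on every fold
#' complement and evaluated on the held-out fold; convex weights minimising
#' the cross-validated squared-error risk are found by non-negative least
#' squares on the simplex; the candidates are then refitted on all data.
#' With a single candidate the weight vector is `1` and the cross-validation
#' step is skipped.
#'
#' @param x Numeric feature matrix.
#' @param y Labels: 0/1 for `task = "binary"`, values in `[0, 1]` for
#'   `task = "continuous"`.
#' @param task `"binary"` or `"continuous"` (continuous-in-\[0,1\]).
#' @param learners List of [learner_spec()] objects.
#' @param n_folds Number of cross-validation folds.
#' @param seed Seed controlling fold assignment and stochastic learners.
#' @param foldid Optional explicit fold assignment (length `nrow(x)`); when
#'   supplied, results are invariant to row permutations that carry `foldid`
#'   along.
#' @return An object of class `superlearner` with elements `weights`,
#'   `cv_risk` (per candidate), `ensemble_cv_risk`, `fits`, `foldid`,
#'   `degenerate`.
#' @export
fit_superlearner <- function(x, y, task = c("binary", "continuous"),
                             learners = default_learners(), n_folds = 10L,
                             seed = 1L, foldid = NULL) {
  task <- match.arg(task)
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (length(learners) < 1L) stop("need at least one learner", call. = FALSE)
  if (inherits(learners, "learner_spec")) learners <- list(learners)

  if (length(unique(y)) == 1L) {
    fits <- list(structure(list(constant = y[1]), class = "fit_constant"))
    return(structure(list(
      weights = 1, cv_risk = NA_real_, ensemble_cv_risk = NA_real_,
      fits = fits, foldid = NULL, task = task, degenerate = TRUE,
      note = "single-class labels: constant prediction", seed = seed),
      class = "superlearner"))
  }
  if (n < 2L * n_folds) {
    stop(sprintf("too few rows (%d) for %d-fold cross-validation", n, n_folds),
         call. = FALSE)
  }

  k <- length(learners)
  if (k == 1L) {
    fit <- fit_learner(learners[[1]], x, y, task, sub_seed(seed, "refit1"))
    return(structure(list(
      weights = 1, cv_risk = NA_real_, ensemble_cv_risk = NA_real_,
      fits = list(fit), foldid = foldid, task = task, degenerate = FALSE,
      learners = learners, yrange = range(y), seed = seed),
      class = "superlearner"))
  }

  if (is.null(foldid)) {
    foldid <- with_seed(sub_seed(seed, "folds"),
                        sample(rep_len(seq_len(n_folds), n)))
  }
  n_folds <- max(foldid)
  z <- matrix(NA_real_, n, k)
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    if (length(unique(y[tr])) == 1L) {
      z[!tr, ] <- y[tr][1]
      next
    }
    for (j in seq_len(k)) {
      fit <- fit_learner(learners[[j]], x[tr, , drop = FALSE], y[tr], task,
                         sub_seed(seed, paste0("cv", f, "_", j)))
      z[!tr, j] <- predict_learner(fit, x[!tr, , drop = FALSE])
    }
  }
  z <- clip(z, 0, 1)
  w <- tryCatch(pracma::lsqnonneg(z, y)$x, error = function(e) rep(NA_real_, k))
  cv_risk <- colMeans((z - y)^2)
  if (any(!is.finite(w)) || sum(w) <= 0) {
    w <- as.numeric(seq_len(k) == which.min(cv_risk))
  }
  w <- w / sum(w)
  ensemble_cv_risk <- mean((as.numeric(z %*% w) - y)^2)
  if (ensemble_cv_risk > min(cv_risk) + 1e-9) {      # simplex-vertex fallback
    w <- as.numeric(seq_len(k) == which.min(cv_risk))
    ensemble_cv_risk <- min(cv_risk)
  }

  fits <- lapply(seq_len(k), function(j) {
    fit_learner(learners[[j]], x, y, task, sub_seed(seed, paste0("refit", j)))
  })
  structure(list(weights = w, cv_risk = cv_risk,
                 ensemble_cv_risk = ensemble_cv_risk, fits = fits,
                 foldid = foldid, task = task, degenerate = FALSE,
                 learners = learners, yrange = range(y), seed = seed),
            class = "superlearner")
}

#' Predict from a fitted super learner
#'
#' Convex combination of the refitted candidates' predictions; binary-task
#' output is clipped to `[1e-6, 1 - 1e-6]`, continuous-task output to
#' `[0, 1]`.
#'
#' @param object A [fit_superlearner()] result.
#' @param newdata Feature matrix with the same columns as the training
#'   features.
#' @param ... Unused.
#' @export
predict.superlearner <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- numeric(nrow(newdata))
  for (j in seq_along(object$fits)) {
    if (object$weights[j] > 0) {
      p <- p + object$weights[j] * predict_learner(object$fits[[j]], newdata)
    }
  }
  if (object$task == "binary") {
    clip(p, 1e-6, 1 - 1e-6)
  } else {
    # clip to the training-label range (within [0,1] when labels are);
    # sequential pseudo-outcomes may legitimately exceed the unit interval
    r <- object$yrange %||% c(0, 1)
    clip(p, r[1], r[2])
  }
}

#' @export
print.superlearner <- function(x, ...) {
  cat("<superlearner>", x$task, "task\n")
  if (x$degenerate) {
    cat("  degenerate:", x$note, "\n")
    return(invisible(x))
  }
  ids <- vapply(x$learners, function(l) l$id, "")
  df <- data.frame(learner = ids, weight = round(x$weights, 4),
                   cv_risk = round(x$cv_risk, 6))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export super-learner weights and risks as a table
#'
#' @param model A fitted [fit_superlearner()] object.
#' @param path Optional CSV path.
#' @return Data frame of candidate ids, weights and CV risks.
#' @export
superlearner_table <- function(model, path = NULL) {
  ids <- if (is.null(model$learners)) "constant" else
    vapply(model$learners, function(l) l$id, "")
  df <- data.frame(learner = ids, weight = model$weights,
                   cv_risk = model$cv_risk,
                   ensemble_cv_risk = model$ensemble_cv_risk)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
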