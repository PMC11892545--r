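#' Control settings for the policy-effect estimators
#'
#' @param outcome_learners,ratio_learners,censor_learners Learner sets
#'   (lists of [learner_spec()]) for the sequential outcome regressions, the
#'   density-ratio classifiers and the censoring model. Default: the
#'   ridge + lasso + random-forest ensemble for all three.
#' @param cf_folds Cross-fitting folds for the final estimator (default 5:
#'   nuisances are trained on the 4/5 complement and evaluated in-fold).
#' @param outcome_folds Cross-validation folds inside the outcome
#'   super learners (default 10).
#' @param ratio_folds,censor_folds Cross-validation folds inside the
#'   treatment/ratio and censoring super learners (default 2).
#' @param censor_floor Lower clip for estimated observation probabilities
#'   (default 0.01, bounding any censoring factor by 100).
#' @param trunc Optional upper quantile at which density ratios are truncated
#'   (default `NULL`: no truncation; weights are checked, not truncated).
#' @param stabilize_ratios Normalise each year's density ratios to mean 1 over
#'   the at-risk set (stabilized weights; the population mean of the true
#'   ratio is 1, so this removes multiplicative estimation drift without
#'   changing the limit).
#' @param positivity_bound Cumulative-weight level above which a positivity
#'   warning record is attached to results (estimation proceeds).
#' @return A list of class `lmtp_control`.
#' @export
lmtp_control <- function(outcome_learners = default_learners(),
                         ratio_learners = default_learners(),
                         censor_learners = default_learners(),
                         cf_folds = 5L, outcome_folds = 10L,
                         ratio_folds = 2L, censor_folds = 2L,
                         censor_floor = 0.01, trunc = NULL,
                         stabilize_ratios = TRUE,
                         positivity_bound = 100) {
  structure(list(outcome_learners = outcome_learners,
                 ratio_learners = ratio_learners,
                 censor_learners = censor_learners,
                 cf_folds = as.integer(cf_folds),
                 outcome_folds = as.integer(outcome_folds),
                 ratio_folds = as.integer(ratio_folds),
                 censor_folds = as.integer(censor_folds),
                 censor_floor = censor_floor, trunc = trunc,
                 stabilize_ratios = isTRUE(stabilize_ratios),
                 positivity_bound = positivity_bound),
            class = "lmtp_control")
}

# ---- shared preparation ----------------------------------------------------

# Builds the reusable estimation state: feature blocks, cross-fitting fold
# assignment, and cross-fitted observation probabilities P(O_{t+1}=1|H_t,A_t).
# Censoring probabilities and density ratios do not depend on the horizon, so
# run_analysis() shares one prep across horizons and policies.
lmtp_prep <- function(data, control = lmtp_control(), seed = 1L) {
  data <- as_lmtp_data(data)
  n <- data$n; tau <- data$tau
  blocks <- feature_blocks(data)
  foldid <- with_seed(sub_seed(seed, "cf_folds"),
                      sample(rep_len(seq_len(control$cf_folds), n)))
  if (n < 2L * control$cf_folds) foldid <- rep(1L, n)

  pC <- matrix(1, n, tau)   # P(O_{t+1} = 1 | H_t, A_t, O_t = 1)
  any_cens <- any(data$O[, -1L] == 0L, na.rm = TRUE)
  if (any_cens) {
    for (t in seq_len(tau)) {
      obs_t <- data$O[, t] == 1L
      if (!any(data$O[obs_t, t + 1L] == 0L)) next
      H <- cbind(history_matrix(blocks, t), blocks$Xn[[t]])
      lab <- data$O[, t + 1L]
      for (f in unique(foldid)) {
        tr <- obs_t & foldid != f
        ev <- obs_t & foldid == f
        if (!any(ev)) next
        if (!any(tr)) tr <- obs_t
        sl <- fit_superlearner(H[tr, , drop = FALSE], lab[tr], "binary",
                               control$censor_learners, control$censor_folds,
                               seed = sub_seed(seed, paste0("cens", t, "_", f)))
        pC[ev, t] <- predict(sl, H[ev, , drop = FALSE])
      }
      pC[!obs_t, t] <- NA_real_
    }
    pC <- clip(pC, control$censor_floor, 1)
  }
  structure(list(data = data, blocks = blocks, foldid = foldid, pC = pC,
                 any_cens = any_cens, control = control, seed = seed,
                 ratios = new.env(parent = emptyenv())),
            class = "lmtp_prep")
}

# assigned treatment matrix under a policy, deterministic given prep seed
assigned_matrix <- function(prep, policy) {
  apply_policy(prep$data$X, policy,
               seed = policy$rng_seed %||% sub_seed(prep$seed, "policy_rng"))
}

# ---- density ratios --------------------------------------------------------

#' Estimate policy density ratios by the classification trick
#'
#' For every treatment year each at-risk, observed person contributes two
#' stacked records with identical history: one carrying the natural treatment
#' (label 0) and one carrying the policy-assigned treatment (label 1). A
#' cross-fitted classifier on (history, treatment) then yields the density
#' ratio at the natural record as the odds `p / (1 - p)`. Where applicable the
#' ratio is multiplied by the censoring factor
#' `1\{O_{t+1} = 1\} / P(O_{t+1} = 1 | H_t, A_t)`.
#'
#' @param panel A panel, `lmtp_data` list, or an internal prep object.
#' @param policy A [policy_spec()].
#' @param control An [lmtp_control()].
#' @param seed Master seed (cross-fitting folds, learners, policy draws).
#' @return An object of class `ratio_estimates`: matrices `r` (ratio including
#'   the censoring factor), `r_cls` (classifier odds alone) and
#'   `censor_factor`, each persons x years with `NA` off the at-risk set.
#' @export
estimate_density_ratios <- function(panel, policy, control = lmtp_control(),
                                    seed = 1L) {
  prep <- if (inherits(panel, "lmtp_prep")) panel else
    lmtp_prep(panel, control, seed)
  key <- paste(policy$id, policy$history_semantics, policy$mix_probability,
               policy$rng_seed %||% "")
  if (!is.null(prep$ratios[[key]])) return(prep$ratios[[key]])

  data <- prep$data; control <- prep$control
  n <- data$n; tau <- data$tau
  Xasg <- assigned_matrix(prep, policy)
  r_cls <- matrix(NA_real_, n, tau)
  notes <- character(0)

  for (t in seq_len(tau)) {
    at_risk <- data$O[, t] == 1L & data$Y[, t] == 0L
    H <- history_matrix(prep$blocks, t)
    # the scenario rules consult the previous *assigned* year, a deterministic
    # function of the natural history; expose it (and its interactions with
    # the current treatment) to the classifier so even plain GLMs can
    # represent the policy's conditional structure
    P <- if (t > 1L) treat_dummies(Xasg[, t - 1L], "Aprev_") else NULL
    An <- treat_dummies(data$X[, t])
    Aa <- treat_dummies(Xasg[, t])
    same <- data$X[, t] == Xasg[, t]
    if (all(same[at_risk], na.rm = TRUE)) {
      r_cls[at_risk, t] <- 1   # policy leaves treatment unchanged here
      notes <- c(notes, sprintf("t=%d: policy equals natural; ratios set to 1", t))
      next
    }
    Z <- history_drivers(H, prep$blocks, t)
    for (f in unique(prep$foldid)) {
      tr <- at_risk & prep$foldid != f
      ev <- at_risk & prep$foldid == f
      if (!any(ev)) next
      if (!any(tr)) tr <- at_risk
      Xs <- rbind(ratio_features(H, P, An, tr, Z),
                  ratio_features(H, P, Aa, tr, Z))
      lab <- rep(c(0, 1), each = sum(tr))
      sl <- fit_superlearner(Xs, lab, "binary", control$ratio_learners,
                             control$ratio_folds,
                             seed = sub_seed(prep$seed, paste0("ratio", t, "_", f)))
      p <- predict(sl, ratio_features(H, P, An, ev, Z))
      r_cls[ev, t] <- p / (1 - p)
    }
  }
  if (!is.null(control$trunc)) {
    cap <- stats::quantile(r_cls, control$trunc, na.rm = TRUE)
    r_cls <- pmin(r_cls, cap)
  }
  if (isTRUE(control$stabilize_ratios)) {
    for (t in seq_len(tau)) {
      m <- mean(r_cls[, t], na.rm = TRUE)
      if (is.finite(m) && m > 0) r_cls[, t] <- r_cls[, t] / m
    }
  }
  cfac <- matrix(NA_real_, n, tau)
  for (t in seq_len(tau)) {
    obs_t <- data$O[, t] == 1L
    cfac[obs_t, t] <- (data$O[obs_t, t + 1L] == 1L) / prep$pC[obs_t, t]
  }
  out <- structure(list(r = r_cls * cfac, r_cls = r_cls, censor_factor = cfac,
                        policy = policy$id, foldid = prep$foldid,
                        trunc = control$trunc, notes = notes,
                        assigned = Xasg),
                   class = "ratio_estimates")
  prep$ratios[[key]] <- out
  out
}

#' Cross-fitted censoring (observation) model
#'
#' Estimates `P(O_{t+1} = 1 | H_t, A_t, O_t = 1)` for each treatment year by
#' cross-fitted super learner. With no censoring in the panel all
#' probabilities are 1 and the censoring factor is inert.
#'
#' @inheritParams estimate_density_ratios
#' @return Persons-by-years matrix of observation probabilities (clipped below
#'   at `control$censor_floor`).
#' @export
fit_censoring_model <- function(panel, control = lmtp_control(), seed = 1L) {
  prep <- if (inherits(panel, "lmtp_prep")) panel else
    lmtp_prep(panel, control, seed)
  prep$pC
}

#' Positivity diagnostics for estimated weights
#'
#' Summarises cumulative density-ratio products per horizon: the maximum and
#' the 99th percentile, as a practical-positivity check for extreme weights.
#'
#' @param ratios A [estimate_density_ratios()] result.
#' @return Data frame with one row per horizon.
#' @export
positivity_diagnostics <- function(ratios) {
  r <- ratios$r_cls
  tau <- ncol(r)
  out <- data.frame(horizon = seq_len(tau), max_weight = NA_real_,
                    q99_weight = NA_real_)
  cum <- rep(1, nrow(r))
  for (t in seq_len(tau)) {
    rt <- r[, t]
    cum <- cum * ifelse(is.na(rt), 1, rt)
    out$max_weight[t] <- max(cum, na.rm = TRUE)
    out$q99_weight[t] <- stats::quantile(cum, 0.99, na.rm = TRUE)
  }
  out
}

# Classifier feature map for the density-ratio trick. The policy rules make
# the ratio's dependence on history live inside specific (previous assigned
# treatment x current treatment) cells, so besides main effects the map
# carries those cell indicators and their interactions with a small set of
# history drivers Z (cumulative treated rate, current L block) - without
# them, no main-effects learner can represent the ratio.
ratio_features <- function(H, P, A, rows, Z = NULL) {
  Hr <- H[rows, , drop = FALSE]
  Ar <- A[rows, , drop = FALSE]
  if (is.null(P)) return(cbind(Hr, Ar))
  Pr <- P[rows, , drop = FALSE]
  p_any <- Pr[, 1] + Pr[, 2]
  a_any <- Ar[, 1] + Ar[, 2]
  blocked_any <- p_any * (1 - a_any)      # prev treated, now untreated
  blocked_sup <- Pr[, 1] * (1 - a_any)    # prev SUPRA, now untreated
  out <- cbind(Hr, Pr, Ar,
               pxa_supra = p_any * Ar[, 1], pxa_sub = p_any * Ar[, 2],
               pss = Pr[, 1] * Ar[, 1], pbb = Pr[, 2] * Ar[, 2],
               b_any = blocked_any, b_sup = blocked_sup)
  if (!is.null(Z)) {
    Zr <- Z[rows, , drop = FALSE]
    za <- Zr * blocked_any
    colnames(za) <- paste0("ba_", colnames(Zr))
    zs <- Zr * blocked_sup
    colnames(zs) <- paste0("bs_", colnames(Zr))
    out <- cbind(out, za, zs)
  }
  out
}

# interaction drivers: engineered treated-rate summaries plus the current
# pre-treatment covariates
history_drivers <- function(H, blocks, t) {
  keep <- intersect(c("treat_rate", "treat_rate_logit"), colnames(H))
  Z <- H[, keep, drop = FALSE]
  if (!is.null(blocks$L[[t]])) Z <- cbind(Z, blocks$L[[t]])
  if (ncol(Z) == 0L) NULL else Z
}

# ---- estimators ------------------------------------------------------------

#' Estimate counterfactual cumulative incidence under a policy
#'
#' `estimate_sdr()` implements the sequentially doubly robust estimator: with
#' `V_{k+1} = Y_{k+1}` (event-by-horizon flag), recurse for `t = k..1`:
#' regress `V_{t+1}` on `(H_t, A_t)` among at-risk observed persons to get
#' `Q_t`, then set
#' `V_t = Q_t(H_t, A^d_t) + r_t [Q](V_{t+1} - Q_t(H_t, A_t))`,
#' where `A^d_t` is the policy-assigned treatment and `r_t` is the density
#' ratio including the censoring factor (the residual vanishes for persons
#' censored at `t + 1`). Persons with an event before `t` carry `V_t = 1` and
#' are excluded from nuisance fitting. The estimate is the mean of `V_1`, its
#' standard error `sd(V_1) / sqrt(n)` (the efficient-influence-function
#' variance), and all nuisances are cross-fitted on `cf_folds` folds.
#'
#' `estimate_gcomp()` runs the same recursion without the residual term
#' (iterated-regression g-computation; point estimate only), and
#' `estimate_ipw()` is the inverse-probability-weighted cross-check
#' `mean(prod_t r_t * Y_{k+1})` with weights accumulated up to the event.
#'
#' @param panel A panel (`perio_panel`), an `lmtp_data` list, or a prep
#'   object from an earlier call.
#' @param policy A [policy_spec()].
#' @param horizon Horizon `k` in `1..tau`: incidence of an event by year
#'   `k + 1`.
#' @param control An [lmtp_control()].
#' @param seed Master seed.
#' @return An object of class `lmtp_estimate` with elements `psi`, `se`,
#'   `ci`, `scores` (per-person terminal pseudo-outcomes `V_1`), `horizon`,
#'   `policy`, `estimator`, `positivity` (diagnostics table) and `warnings`.
#' @examples
#' cfg <- tiny_dgp_config(tau = 2)
#' d <- periopolicy:::simulate_tiny(cfg, 2000, seed = 1)
#' ctl <- lmtp_control(outcome_learners = list(learner_spec("sat")),
#'                     ratio_learners = list(learner_spec("sat")),
#'                     outcome_folds = 2)
#' estimate_sdr(d, policy_spec("scenario1"), horizon = 2, control = ctl)
#' @export
estimate_sdr <- function(panel, policy, horizon, control = lmtp_control(),
                         seed = 1L) {
  lmtp_core(panel, policy, horizon, control, seed, estimator = "sdr")
}

#' @rdname estimate_sdr
#' @export
estimate_gcomp <- function(panel, policy, horizon, control = lmtp_control(),
                           seed = 1L) {
  lmtp_core(panel, policy, horizon, control, seed, estimator = "gcomp")
}

#' @rdname estimate_sdr
#' @export
estimate_ipw <- function(panel, policy, horizon, control = lmtp_control(),
                         seed = 1L) {
  lmtp_core(panel, policy, horizon, control, seed, estimator = "ipw")
}

lmtp_core <- function(panel, policy, horizon, control, seed, estimator) {
  stopifnot(inherits(policy, "policy_spec"))
  prep <- if (inherits(panel, "lmtp_prep")) panel else
    lmtp_prep(panel, control, seed)
  data <- prep$data; control <- prep$control
  n <- data$n; tau <- data$tau
  k <- as.integer(horizon)
  if (k < 1L || k > tau) {
    stop(sprintf("horizon must be in 1..%d", tau), call. = FALSE)
  }
  ratios <- if (estimator == "gcomp") NULL else
    estimate_density_ratios(prep, policy)
  Xasg <- if (is.null(ratios)) assigned_matrix(prep, policy) else ratios$assigned

  if (estimator == "ipw") {
    res <- ipw_psi(data, ratios, k)
  } else {
    res <- sdr_recursion(prep, policy, k, Xasg, ratios,
                         use_residual = estimator == "sdr")
  }
  psi <- clip(res$psi, 0, 1)
  # influence-function inference is reported for SDR only; g-computation and
  # IPW are point cross-checks
  se <- if (estimator == "sdr") res$se else NA_real_
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else
    c(max(0, psi - 1.96 * se), min(1, psi + 1.96 * se))

  warnings <- character(0)
  pos <- NULL
  if (!is.null(ratios)) {
    pos <- positivity_diagnostics(ratios)
    mw <- max(pos$max_weight[seq_len(k)], na.rm = TRUE)
    if (is.finite(control$positivity_bound) && mw > control$positivity_bound) {
      warnings <- c(warnings, sprintf(
        "possible practical positivity violation: max cumulative weight %.1f exceeds %.1f",
        mw, control$positivity_bound))
    }
  }
  structure(list(psi = psi, se = se, ci = ci, horizon = k,
                 policy = policy$id, estimator = estimator,
                 scores = res$scores, n = n, folds = control$cf_folds,
                 seed = seed, positivity = pos, warnings = warnings,
                 prep = prep),
            class = "lmtp_estimate")
}

# shared SDR / g-computation backward recursion, cross-fitted
sdr_recursion <- function(prep, policy, k, Xasg, ratios, use_residual) {
  data <- prep$data; control <- prep$control
  n <- data$n
  V1 <- rep(NA_real_, n)
  for (f in unique(prep$foldid)) {
    evalset <- prep$foldid == f
    trainset <- if (length(unique(prep$foldid)) == 1L) evalset else !evalset
    V_next <- as.numeric(data$Y[, k + 1L])
    for (t in k:1) {
      at_risk <- data$O[, t] == 1L & data$Y[, t] == 0L
      carried <- data$O[, t] == 1L & data$Y[, t] == 1L
      H <- history_matrix(prep$blocks, t)
      An <- treat_dummies(data$X[, t])
      Aa <- treat_dummies(Xasg[, t])
      fit_rows <- trainset & at_risk & data$O[, t + 1L] == 1L & !is.na(V_next)
      if (!any(fit_rows)) fit_rows <- at_risk & data$O[, t + 1L] == 1L & !is.na(V_next)
      sl <- fit_superlearner(
        cbind(H[fit_rows, , drop = FALSE], An[fit_rows, , drop = FALSE]),
        V_next[fit_rows], "continuous", control$outcome_learners,
        control$outcome_folds,
        seed = sub_seed(prep$seed, paste0("q", k, "_", t, "_", f)))
      pred_rows <- at_risk   # training rows propagate; eval rows pooled at t=1
      Qd <- Qn <- rep(NA_real_, n)
      Qd[pred_rows] <- predict(sl, cbind(H[pred_rows, , drop = FALSE],
                                         Aa[pred_rows, , drop = FALSE]))
      V_t <- rep(NA_real_, n)
      V_t[pred_rows] <- Qd[pred_rows]
      if (use_residual) {
        Qn[pred_rows] <- predict(sl, cbind(H[pred_rows, , drop = FALSE],
                                           An[pred_rows, , drop = FALSE]))
        resid <- V_next - Qn
        rt <- ratios$r[, t]
        contrib <- rt * resid
        contrib[is.na(contrib)] <- 0   # censored at t+1: factor is 0
        V_t[pred_rows] <- V_t[pred_rows] + contrib[pred_rows]
      }
      V_t[carried] <- 1   # event before t: deterministic pseudo-outcome
      V_next <- V_t
    }
    V1[evalset] <- V_next[evalset]
  }
  list(psi = mean(V1), se = stats::sd(V1) / sqrt(n), scores = V1)
}

ipw_psi <- function(data, ratios, k) {
  n <- data$n
  w <- rep(1, n)
  active <- rep(TRUE, n)
  for (t in seq_len(k)) {
    done <- data$Y[, t] == 1L      # event already: freeze weight
    done[is.na(done)] <- FALSE
    active <- active & !done
    rt <- ratios$r[, t]
    rt[is.na(rt)] <- 0             # off observed at-risk set: no contribution
    w[active] <- w[active] * rt[active]
  }
  y <- as.numeric(data$Y[, k + 1L])
  y[is.na(y)] <- 0                 # censored without event: weight already 0
  scores <- w * y
  list(psi = mean(scores), se = NA_real_, scores = scores)
}

#' @export
print.lmtp_estimate <- function(x, ...) {
  cat(sprintf("<lmtp_estimate> %s, policy %s, horizon %d\n",
              toupper(x$estimator), x$policy, x$horizon))
  if (is.na(x$se)) {
    cat(sprintf("  cumulative incidence: %.4f (point cross-check, no se)\n", x$psi))
  } else {
    cat(sprintf("  cumulative incidence: %.4f (se %.4f, 95%% CI %.4f-%.4f)\n",
                x$psi, x$se, x$ci[1], x$ci[2]))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
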