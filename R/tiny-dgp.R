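#' Configure an exactly enumerable validation process
#'
#' A deliberately small discrete-time process used to validate the estimators
#' against exact ground truth: binary treatment (`NONE` vs `SUB`), one binary
#' time-varying confounder, no censoring, and explicit conditional probability
#' tables. The default tables encode treatment-confounder feedback (the
#' confounder responds to past treatment and drives future treatment) and a
#' protective treatment effect on the yearly event hazard.
#'
#' Tables are indexed `[L + 1, A_prev + 1]` (treatment `[L_t + 1, A_prev + 1]`,
#' confounder transition `[L_prev + 1, A_prev + 1]`, hazard `[L_t + 1, A_t + 1]`),
#' with `A_0 = 0`.
#'
#' @param tau Number of treatment years (1, 2 or 3).
#' @param p_L1 Probability the confounder starts at 1.
#' @param p_A List of `tau` 2x2 matrices: treatment probability given
#'   (`L_t`, `A_{t-1}`).
#' @param p_L List of `tau` 2x2 matrices (first entry unused): confounder
#'   transition probability given (`L_{t-1}`, `A_{t-1}`).
#' @param p_Y List of `tau` 2x2 matrices: event hazard for year `t + 1` given
#'   (`L_t`, `A_t`), among the event-free.
#' @return An object of class `tiny_dgp_config`.
#' @export
tiny_dgp_config <- function(tau = 2L, p_L1 = 0.5,
                            p_A = NULL, p_L = NULL, p_Y = NULL) {
  tau <- as.integer(tau)
  if (!tau %in% 1:3) stop_config("tau", "must be 1, 2 or 3")
  m <- function(v) matrix(v, 2, 2)   # by column: (L=0,A=0),(L=1,A=0),(L=0,A=1),(L=1,A=1)
  if (is.null(p_A)) {
    p_A <- rep(list(m(c(0.30, 0.60, 0.55, 0.80))), tau)
  }
  if (is.null(p_L)) {
    p_L <- c(list(NULL), rep(list(m(c(0.25, 0.55, 0.45, 0.70))), max(tau - 1L, 0L)))
  }
  if (is.null(p_Y)) {
    p_Y <- rep(list(m(c(0.16, 0.26, 0.09, 0.17))), tau)
  }
  cfg <- structure(list(tau = tau, p_L1 = p_L1, p_A = p_A, p_L = p_L, p_Y = p_Y),
                   class = "tiny_dgp_config")
  validate_tiny_config(cfg)
  cfg
}

validate_tiny_config <- function(cfg) {
  chk <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop_config(nm, "probabilities must lie in [0, 1]")
    }
  }
  chk(cfg$p_L1, "p_L1")
  for (t in seq_len(cfg$tau)) {
    chk(cfg$p_A[[t]], sprintf("p_A[[%d]]", t))
    chk(cfg$p_Y[[t]], sprintf("p_Y[[%d]]", t))
    if (t > 1L) chk(cfg$p_L[[t]], sprintf("p_L[[%d]]", t))
  }
  if (4^cfg$tau * 2^cfg$tau > 1e6) stop_config("tau", "state space too large to enumerate")
  invisible(cfg)
}

# simulate the tiny process; returns an lmtp_data list (see as_lmtp_data).
# policy, when given, intervenes exactly as in simulate_cohort(): natural
# draws from the treatment model under the intervened history, transformed
# year by year; covariates respond to the assigned value.
simulate_tiny <- function(config, n, seed, policy = NULL, keep_truth = FALSE) {
  stopifnot(inherits(config, "tiny_dgp_config"))
  with_seed(sub_seed(seed, "tiny"), {
    tau <- config$tau
    L <- matrix(0L, n, tau)
    Anat <- Aasg <- matrix(0L, n, tau)
    Y <- matrix(0L, n, tau + 1L)
    event <- rep(FALSE, n)
    gA <- matrix(NA_real_, n, tau)
    for (t in seq_len(tau)) {
      L[, t] <- if (t == 1L) as.integer(stats::runif(n) < config$p_L1) else
        as.integer(stats::runif(n) <
                     config$p_L[[t]][cbind(L[, t - 1L] + 1L, Aasg[, t - 1L] + 1L)])
      aprev <- if (t == 1L) rep(0L, n) else Aasg[, t - 1L]
      pa <- config$p_A[[t]][cbind(L[, t] + 1L, aprev + 1L)]
      gA[, t] <- pa
      Anat[, t] <- as.integer(stats::runif(n) < pa)
      if (is.null(policy)) {
        Aasg[, t] <- Anat[, t]
      } else {
        lev <- c("NONE", "SUB")
        asg <- policy_step(
          policy, lev[Anat[, t] + 1L],
          prev_assigned = if (t == 1L) rep(NA_character_, n) else lev[Aasg[, t - 1L] + 1L],
          prev_natural = if (t == 1L) rep(NA_character_, n) else lev[Anat[, t - 1L] + 1L],
          u = stats::runif(n))
        Aasg[, t] <- as.integer(asg == "SUB")
      }
      h <- config$p_Y[[t]][cbind(L[, t] + 1L, Aasg[, t] + 1L)]
      event <- event | (stats::runif(n) < h)
      Y[, t + 1L] <- as.integer(event)
    }
    lev <- c("NONE", "SUB")
    out <- list(
      n = n, tau = tau, C = NULL,
      L = lapply(seq_len(tau), function(t) data.frame(L = L[, t])),
      W = NULL,
      X = matrix(lev[Aasg + 1L], n, tau),
      O = matrix(1L, n, tau + 1L),
      Y = Y
    )
    class(out) <- "lmtp_data"
    if (keep_truth) attr(out, "treatment_prob") <- gA
    out
  })
}

#' Exact counterfactual cumulative incidence by enumeration
#'
#' Sums trajectory probabilities of the [tiny_dgp_config()] process under the
#' intervened law implied by a [policy_spec()]. Stochastic policies
#' (scenario 3) are handled by summing over the policy's own randomisation.
#'
#' @param config A [tiny_dgp_config()].
#' @param policy A [policy_spec()].
#' @param horizon Horizon `k` in `1..tau`: probability of an event by year
#'   `k + 1`.
#' @return A `truth_estimate` with `mc_se = 0`.
#' @export
truth_by_enumeration <- function(config, policy, horizon) {
  stopifnot(inherits(config, "tiny_dgp_config"), inherits(policy, "policy_spec"))
  if (horizon < 1L || horizon > config$tau) {
    stop(sprintf("horizon must be in 1..%d", config$tau), call. = FALSE)
  }
  lev <- c("NONE", "SUB")
  # rows: partial trajectories; surv = P(no event through current year | path)
  paths <- data.frame(prob = 1, surv = 1, Lprev = NA_integer_,
                      Anat_prev = NA_integer_, Aasg_prev = NA_integer_)
  for (t in seq_len(horizon)) {
    new <- vector("list", 0L)
    for (i in seq_len(nrow(paths))) {
      row <- paths[i, ]
      pl <- if (t == 1L) config$p_L1 else
        config$p_L[[t]][row$Lprev + 1L, row$Aasg_prev + 1L]
      for (l in 0:1) {
        p_l <- if (l == 1L) pl else 1 - pl
        if (p_l == 0) next
        aprev <- if (t == 1L) 0L else row$Aasg_prev
        pa <- config$p_A[[t]][l + 1L, aprev + 1L]
        for (anat in 0:1) {
          p_a <- if (anat == 1L) pa else 1 - pa
          if (p_a == 0) next
          # policy randomisation: branch over u < mix (take) vs not (keep)
          branches <- if (policy$id == "scenario3") {
            list(c(u = 0, w = policy$mix_probability),
                 c(u = 1, w = 1 - policy$mix_probability))
          } else list(c(u = 0, w = 1))
          for (br in branches) {
            if (br["w"] == 0) next
            asg <- policy_step(
              policy, lev[anat + 1L],
              prev_assigned = if (t == 1L) NA_character_ else lev[row$Aasg_prev + 1L],
              prev_natural = if (t == 1L) NA_character_ else lev[row$Anat_prev + 1L],
              u = br[["u"]])
            a <- as.integer(asg == "SUB")
            h <- config$p_Y[[t]][l + 1L, a + 1L]
            new[[length(new) + 1L]] <- data.frame(
              prob = row$prob * p_l * p_a * br[["w"]],
              surv = row$surv * (1 - h),
              Lprev = l, Anat_prev = anat, Aasg_prev = a)
          }
        }
      }
    }
    paths <- do.call(rbind, new)
  }
  value <- 1 - sum(paths$prob * paths$surv)
  structure(list(value = value, mc_se = 0, policy = policy$id,
                 horizon = as.integer(horizon), n_mc = nrow(paths),
                 paths = paths),
            class = "truth_estimate")
}

#' Ground-truth counterfactual incidence by intervened simulation
#'
#' Simulates the data-generating process with treatment assigned by the
#' policy at every year (downstream covariates responding to the assigned
#' value) and censoring disabled, and returns the Monte-Carlo mean of the
#' event-by-horizon flag with its binomial standard error.
#'
#' @param config A [dgp_config()] or [tiny_dgp_config()].
#' @param policy A [policy_spec()].
#' @param horizon Horizon `k` (event by year `k + 1`).
#' @param n_mc Number of simulated persons.
#' @param seed Seed for the Monte-Carlo draw.
#' @return A `truth_estimate`.
#' @export
truth_by_simulation <- function(config, policy, horizon, n_mc = 100000L, seed = 1L) {
  stopifnot(inherits(policy, "policy_spec"))
  if (inherits(config, "tiny_dgp_config")) {
    if (horizon < 1L || horizon > config$tau) {
      stop(sprintf("horizon must be in 1..%d", config$tau), call. = FALSE)
    }
    dat <- simulate_tiny(config, n_mc, seed, policy = policy)
    y <- dat$Y[, horizon + 1L]
  } else {
    tau <- config$n_years - 1L
    if (horizon < 1L || horizon > tau) {
      stop(sprintf("horizon must be in 1..%d", tau), call. = FALSE)
    }
    cfg <- config
    cfg$n_persons <- as.integer(n_mc)
    panel <- simulate_cohort(cfg, seed = seed, policy = policy, censoring = FALSE)
    y <- panel[[paste0("Y_", 2010L + horizon + 1L)]]
  }
  p <- mean(y)
  structure(list(value = p, mc_se = sqrt(p * (1 - p) / n_mc),
                 policy = policy$id, horizon = as.integer(horizon),
                 n_mc = as.integer(n_mc)),
            class = "truth_estimate")
}

#' @export
print.truth_estimate <- function(x, ...) {
  cat(sprintf("<truth_estimate> policy %s, horizon %d: %.4f (mc se %.4f, n %d)\n",
              x$policy, x$horizon, x$value, x$mc_se, x$n_mc))
  invisible(x)
}

#' Export truth estimates as a table
#'
#' @param truths A list of `truth_estimate` objects.
#' @param path Optional CSV path; when given the table is also written there.
#' @param seed Seed to record alongside (for simulation truths).
#' @return A data frame with one row per estimate.
#' @export
truth_table <- function(truths, path = NULL, seed = NA_integer_) {
  df <- do.call(rbind, lapply(truths, function(x) {
    data.frame(policy = x$policy, horizon = x$horizon, value = x$value,
               mc_se = x$mc_se, n_mc = x$n_mc, seed = seed)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
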