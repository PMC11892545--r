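#' Simulate a synthetic registry cohort
#'
#' Generates a one-row-per-person longitudinal panel under the data-generating
#' process of [dgp_config()]. Within each follow-up year `t` the generation
#' order is: pre-treatment covariates `L_t` (income percentile, diabetes),
#' treatment `X_t`, post-treatment service covariates `W_t`, the event
#' indicator for year `t + 1`, and finally censoring effective at the end of
#' the year (a censored person contributes all of year `t`). The service
#' covariates enter the treatment model only with a one-year lag. The outcome
#' hazard depends only on covariates observed by the analysis, so the
#' estimators' identifying assumptions hold by construction at
#' `confounding_dial = 0`.
#'
#' Passing a [policy_spec()] simulates the *intervened* process: at every year
#' the natural treatment is drawn from the treatment model given the
#' intervened history, the policy transforms it, and all downstream covariates
#' and hazards respond to the assigned value. This is the basis of the
#' simulation truth oracle ([truth_by_simulation()]).
#'
#' @param config A [dgp_config()].
#' @param seed Integer seed; the same `(config, seed)` pair always yields an
#'   identical panel.
#' @param policy Optional [policy_spec()] to intervene on treatment.
#' @param censoring Set `FALSE` to disable loss to follow-up (used when
#'   defining ground truth).
#' @param keep_truth If `TRUE`, attach the true per-person-year event hazards
#'   and observation (non-censoring) probabilities as attributes
#'   `"true_event_hazard"` and `"true_obs_prob"`.
#' @return A `data.frame` of class `perio_panel`: baseline block, then yearly
#'   blocks with 4-digit calendar-year suffixes (`L_income_2011`,
#'   `L_diabetes_2011`, `X_2011`, `W_exam_2011`, ..., `O_2011`, `Y_2012`,
#'   ...). Treatment columns hold [treatment_levels()] strings; `O` is the
#'   monotone non-increasing under-observation flag and `Y` the monotone
#'   non-decreasing first-extraction flag (`NA` once unobserved).
#' @examples
#' cfg <- dgp_config(n_persons = 500)
#' panel <- simulate_cohort(cfg, seed = 1)
#' summarize_cohort(panel)
#' @export
simulate_cohort <- function(config, seed = NULL, policy = NULL,
                            censoring = TRUE, keep_truth = FALSE) {
  stopifnot(inherits(config, "dgp_config"))
  validate_dgp_config(config)
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("simulate_cohort() needs a seed", call. = FALSE)
  if (!is.null(policy)) stopifnot(inherits(policy, "policy_spec"))
  with_seed(sub_seed(seed, "cohort"),
            simulate_cohort_impl(config, policy, censoring, keep_truth))
}

simulate_cohort_impl <- function(config, policy, censoring, keep_truth) {
  n <- config$n_persons
  tau <- config$n_years - 1L          # treatment years 1..tau
  years <- 2010L + seq_len(config$n_years)
  bd <- config$baseline_dists
  hd <- config$history_dists
  tm <- config$treatment_model
  cm <- config$covariate_models
  om <- config$outcome_model
  sm <- config$censoring_model

  if (n == 0L) return(empty_panel(config))

  ## ---- baseline block -------------------------------------------------
  sex <- ifelse(stats::runif(n) < bd$sex_male, "male", "female")
  origin <- ifelse(stats::runif(n) < bd$origin_danish, "danish", "other")
  educ <- sample(names(bd$education), n, TRUE, prob = bd$education)
  region <- sample(names(bd$region), n, TRUE, prob = bd$region)

  nh <- hd$n_hist_years
  qs <- function(sh) stats::rbeta(n, sh[1], sh[2])
  q_supra <- qs(hd$q_supra); q_sub <- qs(hd$q_sub); q_surg <- qs(hd$q_surgery)
  q_exam <- qs(hd$q_exam); q_endo <- qs(hd$q_endo)
  q_prev <- qs(hd$q_prevention); q_rad <- qs(hd$q_radiograph)

  hist_years_supra <- stats::rbinom(n, nh, q_supra)
  hist_years_sub <- stats::rbinom(n, nh, q_sub)
  hist_years_surgery <- stats::rbinom(n, nh, q_surg)
  hist_years_exam <- stats::rbinom(n, nh, q_exam)
  hist_years_endo <- stats::rbinom(n, nh, q_endo)
  hist_years_prevention <- stats::rbinom(n, nh, q_prev)
  hist_years_radiograph <- stats::rbinom(n, nh, q_rad)

  rst <- hd$restorations
  g_rest <- stats::rgamma(n, shape = rst$shape, rate = rst$shape / rst$mean_per_year)
  hist_restorations <- stats::rpois(n, nh * g_rest * rst$hist_rate_factor)
  hist_extractions <- stats::rnbinom(n, size = hd$extractions$size,
                                     mu = hd$extractions$mu)

  inc_cfg <- hd$income
  u_inc <- 100 * stats::rbeta(n, inc_cfg$beta[1], inc_cfg$beta[2])
  hist_income_sum <- clip(
    nh * (inc_cfg$hist_shrink * u_inc +
            (1 - inc_cfg$hist_shrink) * inc_cfg$hist_center) +
      stats::rnorm(n, 0, inc_cfg$hist_noise_sd),
    0, 100 * nh)

  ## latent person effects (affect treatment/service models only)
  pi_any <- clip(1 - (1 - q_supra) * (1 - q_sub), 1e-4, 1 - 1e-4)
  z_any <- logit(pi_any) - mean_logit_any(hd)
  z_sub <- logit(clip(q_sub, 1e-4, 1 - 1e-4)) - mean_logit(hd$q_sub)
  z_exam <- logit(clip(q_exam, 1e-4, 1 - 1e-4)) - mean_logit(hd$q_exam)
  z_endo <- logit(clip(q_endo, 1e-4, 1 - 1e-4)) - mean_logit(hd$q_endo)
  z_prev <- logit(clip(q_prev, 1e-4, 1 - 1e-4)) - mean_logit(hd$q_prevention)
  z_rad <- logit(clip(q_rad, 1e-4, 1 - 1e-4)) - mean_logit(hd$q_radiograph)
  frailty <- if (config$confounding_dial != 0) stats::rnorm(n) else numeric(n)

  ## ---- storage ---------------------------------------------------------
  L_income <- matrix(NA_real_, n, tau + 1L)
  L_diab <- matrix(NA_integer_, n, tau + 1L)
  X_nat <- matrix(NA_character_, n, tau)
  X_asg <- matrix(NA_character_, n, tau)
  W_exam <- W_prevn <- W_radio <- W_endo <- matrix(NA_integer_, n, tau + 1L)
  W_rest <- matrix(NA_integer_, n, tau + 1L)
  O <- matrix(0L, n, tau + 1L); O[, 1L] <- 1L
  Y <- matrix(NA_integer_, n, tau + 1L)   # Y[, t] = event by year t (t >= 2)
  haz_true <- matrix(NA_real_, n, tau)
  obs_true <- matrix(NA_real_, n, tau)

  alive <- rep(TRUE, n)        # under observation
  event <- rep(FALSE, n)       # first extraction occurred
  prev_any <- stats::runif(n) < pi_any   # unobserved year-2010 treatment state
  prev_sub <- rep(FALSE, n)
  prev_exam <- stats::runif(n) < clip(q_exam, 0, 1)  # year-2010 exam state

  svc <- cm$services
  svc_year_logit <- function(s, t) {
    w <- if (tau > 1L) (t - 1) / (tau - 1L) else 0
    s$logit_2011 + w * (s$logit_2020 - s$logit_2011)
  }

  for (t in seq_len(tau + 1L)) {
    idx <- which(alive)
    if (length(idx) == 0L && t > 1L) break

    ## L_t: income percentile and absorbing diabetes flag
    if (t == 1L) {
      L_income[, 1L] <- reflect(u_inc + stats::rnorm(n, 0, cm$income_rw$init_sd), 0, 100)
      p_d <- stats::plogis(cm$diabetes$init_intercept +
                             cm$diabetes$init_b_income * (L_income[, 1L] / 100 - 0.65))
      L_diab[, 1L] <- as.integer(stats::runif(n) < p_d)
    } else {
      L_income[idx, t] <- reflect(L_income[idx, t - 1L] + cm$income_rw$drift +
                                    stats::rnorm(length(idx), 0, cm$income_rw$sd), 0, 100)
      newp <- stats::plogis(cm$diabetes$hazard_intercept +
                              cm$diabetes$hazard_b_income *
                                (L_income[idx, t] / 100 - 0.65))
      onset <- stats::runif(length(idx)) < newp
      L_diab[idx, t] <- as.integer(L_diab[idx, t - 1L] == 1L | onset)
    }
    ci <- L_income[, t] / 100 - 0.65

    if (t <= tau) {
      ## X_t: natural multinomial draw, then (optionally) the policy
      lp_any <- tm$intercept + tm$b_propensity * z_any +
        tm$b_prev_any * as.numeric(prev_any) +
        tm$b_income * ci + tm$b_diabetes * L_diab[, t] +
        tm$b_exam_lag * as.numeric(prev_exam) +
        config$confounding_dial * frailty
      # bounded away from 0/1: even the most regular attenders skip a year
      # occasionally, which also guarantees practical positivity for the
      # consecutive-year policies
      pb <- tm$p_bounds
      p_any <- clip(stats::plogis(lp_any), pb[1], pb[2])
      any_t <- stats::runif(n) < p_any
      lp_sub <- tm$sub$intercept + tm$sub$b_propensity * z_sub +
        tm$sub$b_prev_sub * as.numeric(prev_sub)
      sub_t <- stats::runif(n) < stats::plogis(lp_sub)
      X_nat[, t] <- ifelse(any_t, ifelse(sub_t, "SUB", "SUPRA"), "NONE")
      if (is.null(policy)) {
        X_asg[, t] <- X_nat[, t]
      } else {
        u_pol <- stats::runif(n)
        X_asg[, t] <- policy_step(
          policy, X_nat[, t],
          prev_assigned = if (t == 1L) rep(NA_character_, n) else X_asg[, t - 1L],
          prev_natural = if (t == 1L) rep(NA_character_, n) else X_nat[, t - 1L],
          u = u_pol)
      }
      treated_t <- X_asg[, t] != "NONE"

      ## W_t: post-treatment service covariates (depend on same-year X)
      draw_svc <- function(s, z) {
        as.integer(stats::runif(n) <
                     stats::plogis(svc_year_logit(s, t) + s$b_z * z +
                                     s$b_treat * as.numeric(treated_t)))
      }
      W_exam[, t] <- draw_svc(svc$exam, z_exam)
      W_prevn[, t] <- draw_svc(svc$prevention, z_prev)
      W_endo[, t] <- draw_svc(svc$endodontic, z_endo)
      W_radio[, t] <- draw_svc(svc$radiograph, z_rad)
      mu_rest <- g_rest * exp(cm$restorations$b_treat * as.numeric(treated_t))
      mu_rest[!is.finite(mu_rest)] <- 0   # censored rows; blanked below
      W_rest[, t] <- stats::rpois(n, mu_rest)

      ## event in year t + 1 (hazard measurable w.r.t. H_t and X_t)
      treated_prev <- if (t == 1L) rep(0, n) else as.numeric(X_asg[, t - 1L] != "NONE")
      lp_y <- om$intercept +
        om$b_extraction_history * hist_extractions +
        om$b_income * ci + om$b_diabetes * L_diab[, t] +
        om$b_exam_lag * as.numeric(prev_exam) +
        om$b_educ_primary * as.numeric(educ == "primary") +
        om$theta_treat * (as.numeric(treated_t) + treated_prev) +
        config$confounding_dial * frailty
      h_y <- clip(stats::plogis(lp_y), 1e-8, 1 - 1e-8)
      haz_true[, t] <- h_y
      new_event <- stats::runif(n) < h_y
      new_event[is.na(new_event)] <- FALSE   # censored rows carry NA covariates
      event <- event | new_event
      Y[, t + 1L] <- as.integer(event)

      ## censoring at year end (effective from year t + 1)
      lp_c <- sm$intercept + sm$b_income * ci + sm$b_diabetes * L_diab[, t] +
        sm$b_male * as.numeric(sex == "male")
      h_c <- stats::plogis(lp_c)
      obs_true[, t] <- 1 - h_c
      lost <- censoring & (stats::runif(n) < h_c)
      lost[is.na(lost)] <- FALSE
      alive <- alive & !lost
      O[, t + 1L] <- as.integer(alive)

      prev_any <- X_asg[, t] != "NONE"   # persistence follows the lived history
      prev_sub <- X_asg[, t] == "SUB"
      prev_exam <- W_exam[, t] == 1L
    } else {
      ## terminal year tau + 1: only L is generated; W undefined, no treatment
      W_exam[, t] <- W_prevn[, t] <- W_endo[, t] <- W_radio[, t] <- NA_integer_
      W_rest[, t] <- NA_integer_
    }
  }

  ## blank out years after censoring (monotone missingness); an extraction
  ## observed before loss to follow-up stays known (absorbing event), while
  ## post-censoring event status is undetermined
  last_obs <- rowSums(O)                         # O is monotone
  known_event <- vapply(seq_len(n), function(i) {
    t0 <- last_obs[i]
    t0 >= 2L && Y[i, t0] == 1L
  }, logical(1))
  for (t in 2L:(tau + 1L)) {
    gone <- O[, t] == 0L
    L_income[gone, t] <- NA_real_
    L_diab[gone, t] <- NA_integer_
    Y[gone, t] <- ifelse(known_event[gone], 1L, NA_integer_)
    if (t <= tau) {
      X_nat[gone, t] <- NA_character_
      X_asg[gone, t] <- NA_character_
      W_exam[gone, t] <- W_prevn[gone, t] <- NA_integer_
      W_endo[gone, t] <- W_radio[gone, t] <- W_rest[gone, t] <- NA_integer_
    }
  }

  panel <- data.frame(
    id = seq_len(n), sex = sex, origin = origin, educ = educ, region = region,
    hist_restorations = hist_restorations, hist_extractions = hist_extractions,
    hist_years_supra = hist_years_supra, hist_years_sub = hist_years_sub,
    hist_years_surgery = hist_years_surgery, hist_years_exam = hist_years_exam,
    hist_years_endo = hist_years_endo,
    hist_years_prevention = hist_years_prevention,
    hist_years_radiograph = hist_years_radiograph,
    hist_income_sum = hist_income_sum,
    stringsAsFactors = FALSE
  )
  for (t in seq_len(tau + 1L)) {
    yr <- years[t]
    panel[[paste0("L_income_", yr)]] <- L_income[, t]
    panel[[paste0("L_diabetes_", yr)]] <- L_diab[, t]
    if (t <= tau) {
      panel[[paste0("X_", yr)]] <- X_asg[, t]
      panel[[paste0("W_exam_", yr)]] <- W_exam[, t]
      panel[[paste0("W_prevention_", yr)]] <- W_prevn[, t]
      panel[[paste0("W_radiograph_", yr)]] <- W_radio[, t]
      panel[[paste0("W_endo_", yr)]] <- W_endo[, t]
      panel[[paste0("W_restorations_", yr)]] <- W_rest[, t]
    }
    panel[[paste0("O_", yr)]] <- O[, t]
    if (t >= 2L) panel[[paste0("Y_", yr)]] <- Y[, t]
  }
  class(panel) <- c("perio_panel", "data.frame")
  attr(panel, "years") <- years
  attr(panel, "n_treatment_years") <- tau
  if (keep_truth) {
    attr(panel, "true_event_hazard") <- haz_true
    attr(panel, "true_obs_prob") <- obs_true
    attr(panel, "natural_treatment") <- X_nat
  }
  panel
}

# population mean of logit(1 - (1 - q_supra)(1 - q_sub)) under the config's
# Beta laws, by fixed-grid quadrature (deterministic centering constant)
mean_logit_any <- function(hd) {
  g <- seq(0.0005, 0.9995, length.out = 400)
  ws <- stats::dbeta(g, hd$q_supra[1], hd$q_supra[2])
  wb <- stats::dbeta(g, hd$q_sub[1], hd$q_sub[2])
  ws <- ws / sum(ws); wb <- wb / sum(wb)
  pa <- outer(1 - g, 1 - g)      # (1-qs)(1-qb)
  sum((ws %o% wb) * logit(clip(1 - pa, 1e-4, 1 - 1e-4)))
}

mean_logit <- function(shapes) {
  g <- seq(0.0005, 0.9995, length.out = 800)
  w <- stats::dbeta(g, shapes[1], shapes[2]); w <- w / sum(w)
  sum(w * logit(clip(g, 1e-4, 1 - 1e-4)))
}

empty_panel <- function(config) {
  tau <- config$n_years - 1L
  years <- 2010L + seq_len(config$n_years)
  cols <- c("id", "sex", "origin", "educ", "region",
            "hist_restorations", "hist_extractions", "hist_years_supra",
            "hist_years_sub", "hist_years_surgery", "hist_years_exam",
            "hist_years_endo", "hist_years_prevention",
            "hist_years_radiograph", "hist_income_sum")
  panel <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  panel$sex <- character(0); panel$origin <- character(0)
  panel$educ <- character(0); panel$region <- character(0)
  for (t in seq_len(tau + 1L)) {
    yr <- years[t]
    panel[[paste0("L_income_", yr)]] <- numeric(0)
    panel[[paste0("L_diabetes_", yr)]] <- integer(0)
    if (t <= tau) {
      panel[[paste0("X_", yr)]] <- character(0)
      for (w in c("W_exam_", "W_prevention_", "W_radiograph_", "W_endo_",
                  "W_restorations_")) {
        panel[[paste0(w, yr)]] <- integer(0)
      }
    }
    panel[[paste0("O_", yr)]] <- integer(0)
    if (t >= 2L) panel[[paste0("Y_", yr)]] <- integer(0)
  }
  class(panel) <- c("perio_panel", "data.frame")
  attr(panel, "years") <- years
  attr(panel, "n_treatment_years") <- tau
  panel
}

#' Treatment-history matrix of a panel
#'
#' Extracts the persons-by-years character matrix of treatment values from a
#' panel (columns `X_<year>`).
#'
#' @param panel A panel from [simulate_cohort()] or [read_panel()].
#' @return Character matrix with one column per treatment year.
#' @export
treatment_matrix <- function(panel) {
  xc <- grep("^X_\\d{4}$", names(panel), value = TRUE)
  m <- as.matrix(panel[xc])
  dimnames(m) <- list(NULL, xc)
  m
}
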