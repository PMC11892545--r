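# Shared fixtures, built in code and cached per test run.

fast_control <- function(...) {
  lmtp_control(outcome_learners = glm_learners(),
               ratio_learners = list(learner_spec("ridge", lambda = 0.02)),
               censor_learners = list(learner_spec("ridge", lambda = 0.01)),
               ...)
}

sat_control <- function(...) {
  lmtp_control(outcome_learners = list(learner_spec("sat")),
               ratio_learners = list(learner_spec("sat")),
               censor_learners = list(learner_spec("sat")),
               outcome_folds = 2, ...)
}

.fixtures <- new.env(parent = emptyenv())

# default-config cohort of 20 000 used by calibration and mechanics tests
default_panel <- function() {
  if (is.null(.fixtures$panel)) {
    .fixtures$panel <- simulate_cohort(dgp_config(), seed = 1)
  }
  .fixtures$panel
}

small_panel <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_cohort(dgp_config(n_persons = 400, n_years = 4),
                                       seed = 3)
  }
  .fixtures$small
}

# a two-person hand panel: person 1 treated every year, person 2 never
hand_panel <- function(tau = 4) {
  cfg <- dgp_config(n_persons = 2L, n_years = tau + 1L)
  p <- simulate_cohort(cfg, seed = 1)
  for (t in seq_len(tau)) {
    yr <- 2010L + t
    p[[paste0("X_", yr)]] <- c("SUB", "NONE")
    p[[paste0("O_", yr)]] <- c(1L, 1L)
    if (t >= 2) p[[paste0("Y_", yr)]] <- c(0L, 0L)
  }
  p[[paste0("O_", 2011L + tau)]] <- c(1L, 1L)
  p[[paste0("Y_", 2011L + tau)]] <- c(0L, 0L)
  p
}
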