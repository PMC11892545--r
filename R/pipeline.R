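#' Configure a full analysis run
#'
#' @param dgp A [dgp_config()] used to simulate the cohort, or `NULL` when
#'   `panel_path` is given.
#' @param panel_path Path to a panel CSV ([read_panel()] layout); overrides
#'   `dgp`.
#' @param scenarios Character vector of policy ids to estimate; `"identity"`
#'   (the observed pattern) is always included as the reference.
#' @param horizons Horizons to estimate (default all).
#' @param estimator `"sdr"`, `"gcomp"` or `"ipw"`.
#' @param control An [lmtp_control()].
#' @param outdir Output directory for CSV artifacts, the manifest and plots;
#'   `NULL` to return results without writing.
#' @param seed Master seed; every random draw in the run derives from it.
#' @param plots Write cumulative-incidence plots (failures never fail the run).
#' @return A list of class `run_config`.
#' @export
run_config <- function(dgp = dgp_config(), panel_path = NULL,
                       scenarios = c("scenario1", "scenario2", "scenario3"),
                       horizons = NULL,
                       estimator = c("sdr", "gcomp", "ipw"),
                       control = lmtp_control(), outdir = NULL, seed = 1L,
                       plots = TRUE) {
  estimator <- match.arg(estimator)
  valid <- c("identity", "scenario1", "scenario2", "scenario3")
  bad <- setdiff(scenarios, valid)
  if (length(bad)) {
    stop_config("scenarios", paste("unknown policy id(s):",
                                   paste(bad, collapse = ", ")))
  }
  if (!is.null(panel_path) && !file.exists(panel_path)) {
    stop_config("panel_path", paste("file does not exist:", panel_path))
  }
  structure(list(dgp = dgp, panel_path = panel_path,
                 scenarios = union("identity", scenarios),
                 horizons = horizons, estimator = estimator,
                 control = control, outdir = outdir, seed = as.integer(seed),
                 plots = plots),
            class = "run_config")
}

#' Run the full simulate-policy-estimate-contrast pipeline
#'
#' Simulates (or loads) the cohort, estimates the counterfactual cumulative
#' incidence for every requested policy and horizon on shared cross-fitting
#' folds, contrasts every scenario against the observed (identity) reference
#' via risk differences and risk ratios, and tabulates treated proportions by
#' year under each policy. When `config$outdir` is set, writes
#' `incidence.csv`, `contrasts.csv`, `treated_by_year.csv`, a `manifest.json`
#' from which [rerun_from_manifest()] reproduces the run, and (optionally)
#' cumulative-incidence plots.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `incidence`, `contrasts`, `treated_by_year`,
#'   `fits` and `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  panel <- if (!is.null(config$panel_path)) {
    message("reading panel from ", config$panel_path)
    read_panel(config$panel_path)
  } else {
    message("simulating cohort of ", config$dgp$n_persons, " persons")
    simulate_cohort(config$dgp, seed = sub_seed(seed, "panel"))
  }
  data <- as_lmtp_data(panel)
  horizons <- config$horizons %||% seq_len(data$tau)
  prep <- lmtp_prep(data, config$control, seed = sub_seed(seed, "estimation"))

  fits <- list()
  for (sc in config$scenarios) {
    message("estimating policy ", sc, " at ", length(horizons), " horizon(s)")
    pol <- policy_spec(sc, rng_seed = if (sc == "scenario3")
      sub_seed(seed, "scenario3_policy") else NULL)
    fits[[sc]] <- lmtp_survival(prep, pol, horizons,
                                estimator = config$estimator,
                                seed = sub_seed(seed, "estimation"))
  }
  incidence <- do.call(rbind, lapply(fits, incidence_table))
  rownames(incidence) <- NULL

  contrasts <- NULL
  others <- setdiff(config$scenarios, "identity")
  if (length(others)) {
    contrasts <- do.call(rbind, lapply(others, function(sc) {
      contrast(fits[[sc]], fits[["identity"]])
    }))
    rownames(contrasts) <- NULL
  }

  treated <- treated_by_year(panel, config$scenarios, seed)

  manifest <- list(
    package = "periopolicy",
    version = as.character(utils::packageVersion("periopolicy")),
    seed = seed,
    scenarios = config$scenarios,
    horizons = horizons,
    estimator = config$estimator,
    panel_path = config$panel_path,
    dgp = if (is.null(config$panel_path)) dgp_for_manifest(config$dgp) else NULL,
    control = unclass_control(config$control),
    config_hash = rlang::hash(list(config$dgp, config$panel_path,
                                   config$scenarios, horizons,
                                   config$estimator, seed))
  )

  out <- list(incidence = incidence, contrasts = contrasts,
              treated_by_year = treated, fits = fits, manifest = manifest)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(incidence, file.path(config$outdir, "incidence.csv"),
                     row.names = FALSE)
    if (!is.null(contrasts)) {
      utils::write.csv(contrasts, file.path(config$outdir, "contrasts.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(treated, file.path(config$outdir, "treated_by_year.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (isTRUE(config$plots)) {
      try({
        grDevices::png(file.path(config$outdir, "cumulative_incidence.png"),
                       width = 800, height = 600)
        cols <- seq_along(fits)
        plot(fits[[1]], col = cols[1],
             main = "Counterfactual cumulative incidence by policy")
        for (i in seq_along(fits)[-1]) plot(fits[[i]], add = TRUE, col = cols[i])
        graphics::legend("topleft", legend = names(fits), col = cols, lty = 1,
                         pch = 16, bty = "n")
        grDevices::dev.off()
      }, silent = TRUE)
    }
  }
  invisible(out)
}

#' Treated proportions by calendar year under each policy
#'
#' The share of persons under observation receiving subgingival/surgical care
#' and only-supragingival care each year, as observed and under each policy's
#' assigned treatment.
#'
#' @param panel A panel.
#' @param scenarios Policy ids.
#' @param seed Seed for scenario 3's randomisation.
#' @return Data frame: policy, year, proportion SUB, proportion SUPRA,
#'   proportion any.
#' @export
treated_by_year <- function(panel, scenarios = c("identity", "scenario1",
                                                 "scenario2", "scenario3"),
                            seed = 1L) {
  X <- treatment_matrix(panel)
  yrs <- as.integer(sub("^X_", "", colnames(X)))
  do.call(rbind, lapply(scenarios, function(sc) {
    pol <- policy_spec(sc, rng_seed = if (sc == "scenario3")
      sub_seed(seed, "scenario3_policy") else NULL)
    Xa <- apply_policy(X, pol)
    data.frame(policy = sc, year = yrs,
               prop_sub = colMeans(Xa == "SUB", na.rm = TRUE),
               prop_supra = colMeans(Xa == "SUPRA", na.rm = TRUE),
               prop_any = colMeans(Xa != "NONE", na.rm = TRUE),
               row.names = NULL)
  }))
}

#' Re-run an analysis from its manifest
#'
#' Reconstructs the [run_config()] recorded in a `manifest.json` written by
#' [run_analysis()] and repeats the run; with the recorded seed the output
#' CSVs are identical.
#'
#' @param path Path to `manifest.json`.
#' @param outdir Output directory for the repeated run (`NULL`: no files).
#' @return The [run_analysis()] result, invisibly.
#' @export
rerun_from_manifest <- function(path, outdir = NULL) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  # empty JSON objects come back as empty lists; normalise to NULL
  m <- lapply(m, function(v) if (is.list(v) && length(v) == 0L) NULL else v)
  dgp <- if (!is.null(m$dgp)) rebuild_dgp_config(m$dgp) else dgp_config()
  ctl <- if (!is.null(m$control)) do.call(lmtp_control, rebuild_control(m$control))
    else lmtp_control()
  cfg <- run_config(dgp = dgp, panel_path = m$panel_path,
                    scenarios = setdiff(m$scenarios, "identity"),
                    horizons = m$horizons, estimator = m$estimator,
                    control = ctl, outdir = outdir, seed = m$seed)
  run_analysis(cfg)
}

# named category-probability vectors are stored as JSON objects so the
# category labels round-trip
dgp_for_manifest <- function(dgp) {
  x <- unclass(dgp)
  x$baseline_dists$education <- as.list(x$baseline_dists$education)
  x$baseline_dists$region <- as.list(x$baseline_dists$region)
  x
}

rebuild_dgp_config <- function(x) {
  num <- function(v) if (is.list(v)) unlist(v) else v
  x$baseline_dists$education <- num(x$baseline_dists$education)
  x$baseline_dists$region <- num(x$baseline_dists$region)
  dgp_config(n_persons = x$n_persons, n_years = x$n_years,
             baseline_dists = x$baseline_dists,
             history_dists = x$history_dists,
             treatment_model = x$treatment_model,
             covariate_models = x$covariate_models,
             outcome_model = x$outcome_model,
             censoring_model = x$censoring_model,
             confounding_dial = x$confounding_dial %||% 0,
             seed = x$seed)
}

unclass_control <- function(ctl) {
  fam <- function(ls) {
    lapply(ls, function(l) c(list(family = l$family, id = l$id), l$hyper))
  }
  list(outcome_learners = fam(ctl$outcome_learners),
       ratio_learners = fam(ctl$ratio_learners),
       censor_learners = fam(ctl$censor_learners),
       cf_folds = ctl$cf_folds, outcome_folds = ctl$outcome_folds,
       ratio_folds = ctl$ratio_folds, censor_folds = ctl$censor_folds,
       censor_floor = ctl$censor_floor, trunc = ctl$trunc,
       positivity_bound = ctl$positivity_bound)
}

rebuild_control <- function(x) {
  x <- lapply(x, function(v) if (is.list(v) && length(v) == 0L) NULL else v)
  specs <- function(ls) {
    lapply(ls, function(l) {
      if (is.character(l)) return(learner_spec(l))   # bare family name
      do.call(learner_spec, l)
    })
  }
  x$outcome_learners <- specs(x$outcome_learners)
  x$ratio_learners <- specs(x$ratio_learners)
  x$censor_learners <- specs(x$censor_learners)
  x[!vapply(x, is.null, TRUE)]
}
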