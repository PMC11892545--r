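#' Summarise a synthetic registry panel
#'
#' Computes Table-1-style marginals: baseline category proportions and history
#' medians, yearly time-varying marginals among persons under observation,
#' the fraction lost to follow-up by the end of the window, the cumulative
#' event incidence (share of the starting cohort with an event by their last
#' observed year) and the mean/SD of per-person years with any periodontal
#' therapy.
#'
#' @param panel A panel from [simulate_cohort()] or [read_panel()].
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(panel) {
  validate_panel(panel)
  n <- nrow(panel)
  years <- panel_years(panel)
  tau <- length(years) - 1L
  empty <- n == 0L
  prop <- function(x) if (empty) NaN else mean(x)
  med3 <- function(x) if (empty) rep(NaN, 3) else
    unname(stats::quantile(x, c(0.25, 0.5, 0.75)))

  baseline <- list(
    n = n,
    men = prop(panel$sex == "male"),
    danish_origin = prop(panel$origin == "danish"),
    education = if (empty) NaN else prop.table(table(panel$educ)),
    region = if (empty) NaN else prop.table(table(panel$region)),
    hist_income_sum = med3(panel$hist_income_sum),
    hist_restorations = med3(panel$hist_restorations),
    hist_extractions = med3(panel$hist_extractions),
    hist_years_supra = med3(panel$hist_years_supra),
    hist_years_sub = med3(panel$hist_years_sub),
    hist_years_surgery = med3(panel$hist_years_surgery),
    hist_years_exam = med3(panel$hist_years_exam),
    hist_years_endo = med3(panel$hist_years_endo),
    hist_years_prevention = med3(panel$hist_years_prevention),
    hist_years_radiograph = med3(panel$hist_years_radiograph)
  )

  yearly <- data.frame(year = years[seq_len(tau)])
  for (i in seq_len(tau)) {
    yr <- years[i]
    obs <- panel[[paste0("O_", yr)]] == 1L
    sub <- function(col) {
      v <- panel[[col]]
      if (is.null(v)) return(NA_real_)
      if (empty || !any(obs)) NaN else mean(v[obs], na.rm = TRUE)
    }
    yearly$n_observed[i] <- sum(obs)
    yearly$income_median[i] <- if (empty || !any(obs)) NaN else
      stats::median(panel[[paste0("L_income_", yr)]][obs], na.rm = TRUE)
    yearly$diabetes[i] <- sub(paste0("L_diabetes_", yr))
    yearly$exam[i] <- sub(paste0("W_exam_", yr))
    yearly$prevention[i] <- sub(paste0("W_prevention_", yr))
    yearly$endodontic[i] <- sub(paste0("W_endo_", yr))
    yearly$radiograph[i] <- sub(paste0("W_radiograph_", yr))
    yearly$treated_any[i] <- sub_treated(panel, yr, obs, empty)
    yearly$treated_sub[i] <- sub_treated(panel, yr, obs, empty, level = "SUB")
  }

  Ocols <- paste0("O_", years)
  censored <- if (empty) NaN else
    mean(panel[[Ocols[length(Ocols)]]] == 0L)
  Ymat <- as.matrix(panel[paste0("Y_", years[-1])])
  cum_inc <- if (empty) NaN else
    mean(apply(Ymat, 1L, function(y) any(y == 1L, na.rm = TRUE)))

  X <- treatment_matrix(panel)
  ty <- if (empty) list(mean = NaN, sd = NaN) else {
    cnt <- rowSums(X != "NONE", na.rm = TRUE)
    list(mean = mean(cnt), sd = stats::sd(cnt))
  }

  structure(list(baseline = baseline, yearly = yearly,
                 censored_fraction = censored,
                 cumulative_incidence = cum_inc,
                 therapy_years_mean = ty$mean, therapy_years_sd = ty$sd,
                 n = n, undefined = empty),
            class = "cohort_summary")
}

sub_treated <- function(panel, yr, obs, empty, level = NULL) {
  col <- paste0("X_", yr)
  if (is.null(panel[[col]])) return(NA_real_)
  if (empty || !any(obs)) return(NaN)
  x <- panel[[col]][obs]
  if (is.null(level)) mean(x != "NONE", na.rm = TRUE) else
    mean(x == level, na.rm = TRUE)
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat("Synthetic registry cohort summary\n")
  cat(sprintf("  persons: %d\n", x$n))
  if (x$undefined) {
    cat("  (empty panel: counts are 0, proportions undefined)\n")
    return(invisible(x))
  }
  b <- x$baseline
  cat(sprintf("  men: %.1f%%   Danish origin: %.1f%%\n",
              100 * b$men, 100 * b$danish_origin))
  cat(sprintf("  lost to follow-up by end: %.1f%%\n",
              100 * x$censored_fraction))
  cat(sprintf("  cumulative incidence (first extraction): %.1f%%\n",
              100 * x$cumulative_incidence))
  cat(sprintf("  years with any periodontal therapy: mean %.2f (SD %.2f)\n",
              x$therapy_years_mean, x$therapy_years_sd))
  cat("  yearly marginals (among observed):\n")
  print(round(as.data.frame(x$yearly), digits), row.names = FALSE)
  invisible(x)
}
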