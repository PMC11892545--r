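# Internal longitudinal data container and history feature construction.
#
# An `lmtp_data` list holds: n, tau, C (baseline data frame or NULL),
# L (list of per-year data frames, 1..tau), W (list or NULL, 1..tau),
# X (character matrix n x tau of treatment levels), O (n x (tau+1) observation
# flags), Y (n x (tau+1); column t = event by year t, column 1 all zero).
# The history view H_t is the concatenation of C, L_1..L_t, W_1..W_{t-1} and
# treatment dummies for X_1..X_{t-1}; it never contains W_t or any Y.

#' Convert a data set to the estimator's longitudinal layout
#'
#' @param x A panel (`perio_panel`) or an already-converted `lmtp_data` list.
#' @param ... Unused.
#' @return An `lmtp_data` list.
#' @export
as_lmtp_data <- function(x, ...) UseMethod("as_lmtp_data")

#' @export
as_lmtp_data.lmtp_data <- function(x, ...) x

#' @export
as_lmtp_data.default <- function(x, ...) {
  validate_panel(x)
  as_lmtp_data.perio_panel(x, ...)
}

# Categorical baseline covariates are one-of-K encoded (first level dropped);
# count summaries are scaled by 1/10, the income-percentile sum by 1/1000 and
# yearly income percentile to [0, 1] so penalised learners see comparable
# scales.
#' @export
as_lmtp_data.perio_panel <- function(x, ...) {
  years <- panel_years(x)
  tau <- length(years) - 1L
  n <- nrow(x)
  dummy <- function(v, levels) {
    out <- sapply(levels[-1], function(l) as.numeric(v == l))
    if (n <= 1L) out <- matrix(out, nrow = n, dimnames = list(NULL, levels[-1]))
    out
  }
  C <- data.frame(
    male = as.numeric(x$sex == "male"),
    danish = as.numeric(x$origin == "danish"),
    row.names = NULL
  )
  edu_lev <- c("vocational", "primary", "short_cycle", "medium_cycle",
               "long_cycle", "other")
  reg_lev <- c("other", "north_jutland", "central_jutland",
               "southern_denmark", "capital", "zealand")
  C <- cbind(C,
             stats::setNames(as.data.frame(dummy(x$educ, edu_lev)),
                             paste0("educ_", edu_lev[-1])),
             stats::setNames(as.data.frame(dummy(x$region, reg_lev)),
                             paste0("region_", reg_lev[-1])))
  for (h in c("hist_restorations", "hist_extractions", "hist_years_supra",
              "hist_years_sub", "hist_years_surgery", "hist_years_exam",
              "hist_years_endo", "hist_years_prevention",
              "hist_years_radiograph")) {
    C[[h]] <- x[[h]] / 10
  }
  C$hist_income_sum <- x$hist_income_sum / 1000

  L <- lapply(seq_len(tau), function(t) {
    yr <- years[t]
    data.frame(income = x[[paste0("L_income_", yr)]] / 100,
               diabetes = as.numeric(x[[paste0("L_diabetes_", yr)]]))
  })
  W <- lapply(seq_len(tau), function(t) {
    yr <- years[t]
    data.frame(exam = as.numeric(x[[paste0("W_exam_", yr)]]),
               prevention = as.numeric(x[[paste0("W_prevention_", yr)]]),
               radiograph = as.numeric(x[[paste0("W_radiograph_", yr)]]),
               endo = as.numeric(x[[paste0("W_endo_", yr)]]),
               restorations = as.numeric(x[[paste0("W_restorations_", yr)]]))
  })
  X <- treatment_matrix(x)
  O <- as.matrix(x[paste0("O_", years)])
  Y <- cbind(0L, as.matrix(x[paste0("Y_", years[-1])]))
  dimnames(O) <- dimnames(Y) <- NULL
  out <- list(n = n, tau = tau, C = C, L = L, W = W, X = X, O = O, Y = Y)
  class(out) <- "lmtp_data"
  out
}

# Precompute numeric blocks once; H(t) views are cbind'd on demand.
feature_blocks <- function(data) {
  tau <- data$tau
  mat <- function(df, prefix) {
    if (is.null(df) || ncol(df) == 0L) return(NULL)
    m <- as.matrix(df)
    colnames(m) <- paste0(prefix, colnames(df))
    m
  }
  list(
    C = mat(data$C, "C_"),
    L = lapply(seq_len(tau), function(t) mat(data$L[[t]], paste0("L", t, "_"))),
    W = if (is.null(data$W)) NULL else
      lapply(seq_len(tau), function(t) mat(data$W[[t]], paste0("W", t, "_"))),
    Xn = lapply(seq_len(tau), function(t) treat_dummies(data$X[, t], paste0("X", t, "_")))
  )
}

treat_dummies <- function(x, prefix = "A_") {
  m <- cbind(as.numeric(x == "SUPRA"), as.numeric(x == "SUB"))
  colnames(m) <- paste0(prefix, c("SUPRA", "SUB"))
  m
}

# History view H_t (excludes treatment at t itself). Besides the raw blocks,
# two engineered summaries of the treatment history are appended: the
# cumulative any-therapy rate over all recorded years (1990-2010 summaries
# plus follow-up years before t) and its logit. The person-level attendance
# propensity is near-sufficiently summarised by this rate, which keeps plain
# GLM learners close to the true (marginalised) treatment and outcome models.
history_matrix <- function(blocks, t) {
  parts <- c(list(blocks$C),
             blocks$L[seq_len(t)],
             if (!is.null(blocks$W) && t > 1L) blocks$W[seq_len(t - 1L)],
             if (t > 1L) blocks$Xn[seq_len(t - 1L)])
  parts <- parts[!vapply(parts, is.null, TRUE)]
  H <- do.call(cbind, parts)
  n_hist <- 0
  hist_any <- 0
  if (!is.null(blocks$C) &&
      all(c("C_hist_years_supra", "C_hist_years_sub") %in% colnames(blocks$C))) {
    sup <- 10 * blocks$C[, "C_hist_years_supra"]
    sub <- 10 * blocks$C[, "C_hist_years_sub"]
    n_hist <- 21
    hist_any <- sup + sub - sup * sub / n_hist   # expected overlap
  }
  fu_any <- if (t > 1L) {
    Reduce(`+`, lapply(blocks$Xn[seq_len(t - 1L)], function(m) m[, 1] + m[, 2]))
  } else 0
  denom <- n_hist + (t - 1L)
  if (denom > 0) {
    rate <- clip((hist_any + fu_any) / denom, 0, 1)
    H <- cbind(H, treat_rate = rate,
               treat_rate_logit = logit(clip(rate, 0.02, 0.98)))
  }
  H
}
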