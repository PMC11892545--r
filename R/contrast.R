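#' Contrast two policy estimates
#'
#' Risk difference and risk ratio between two counterfactual incidence
#' estimates at the same horizon, with inference from the paired per-person
#' scores (both policies estimated on the same panel and folds): the
#' risk-difference standard error is `sd(V1_a - V1_b) / sqrt(n)` and the
#' risk-ratio interval uses the delta method on the log scale.
#'
#' Can also be called with two [lmtp_survival()] fits, in which case the
#' contrast is computed at every shared horizon.
#'
#' @param a,b `lmtp_estimate` objects at the same horizon (or two
#'   `lmtp_survival` fits on the same panel).
#' @return A data frame of class `lmtp_contrast`: rd, rr and their 95%
#'   confidence intervals per horizon.
#' @export
contrast <- function(a, b) {
  if (inherits(a, "lmtp_survival") && inherits(b, "lmtp_survival")) {
    ks <- intersect(a$horizons, b$horizons)
    out <- do.call(rbind, lapply(ks, function(k) {
      contrast(a$estimates[[paste0("k", k)]], b$estimates[[paste0("k", k)]])
    }))
    return(out)
  }
  stopifnot(inherits(a, "lmtp_estimate"), inherits(b, "lmtp_estimate"))
  if (a$horizon != b$horizon) {
    stop("contrast() requires estimates at the same horizon", call. = FALSE)
  }
  if (length(a$scores) != length(b$scores)) {
    stop("contrast() requires paired per-person scores from the same panel",
         call. = FALSE)
  }
  n <- length(a$scores)
  rd <- a$psi - b$psi
  identical_scores <- isTRUE(all.equal(a$scores, b$scores)) &&
    a$policy == b$policy
  if (identical_scores) {
    rd <- 0
    se_rd <- 0
    rr <- 1
    se_lrr <- 0
  } else {
    d <- a$scores - b$scores
    se_rd <- stats::sd(d) / sqrt(n)
    rr <- a$psi / b$psi
    # delta method: Var(log rr) = Var(mean(Va)/psi_a - mean(Vb)/psi_b)
    se_lrr <- stats::sd(a$scores / a$psi - b$scores / b$psi) / sqrt(n)
  }
  out <- data.frame(
    policy_a = a$policy, policy_b = b$policy, horizon = a$horizon,
    rd = rd, rd_se = se_rd,
    rd_low = rd - 1.96 * se_rd, rd_high = rd + 1.96 * se_rd,
    rr = rr,
    rr_low = rr * exp(-1.96 * se_lrr), rr_high = rr * exp(1.96 * se_lrr))
  class(out) <- c("lmtp_contrast", "data.frame")
  out
}
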