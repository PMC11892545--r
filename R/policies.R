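#' Treatment levels for yearly periodontal therapy
#'
#' The exposure is a three-level categorical variable per calendar year:
#' `"NONE"` (no periodontal treatment), `"SUPRA"` (only supragingival
#' treatment) and `"SUB"` (subgingival or surgical periodontal treatment).
#' `SUPRA` and `SUB` together constitute "any periodontal therapy".
#'
#' @return Character vector of the three valid levels, in this order.
#' @export
treatment_levels <- function() c("NONE", "SUPRA", "SUB")

#' Specify a modified treatment policy
#'
#' Four policies over a yearly treatment history are supported:
#' \describe{
#'   \item{`identity`}{keep the observed treatment.}
#'   \item{`scenario1`}{no periodontal care (of any kind) in two consecutive
#'     years: if the previous year's value is treated and this year's observed
#'     value is treated, assign `NONE`.}
#'   \item{`scenario2`}{no supragingival-only care in two consecutive years:
#'     if the previous year's value is `SUPRA` and this year's observed value
#'     is `SUPRA`, assign `NONE`; `SUB` years are never altered.}
#'   \item{`scenario3`}{extend care into untreated years: if the previous
#'     year (natural history) was treated and this year's observed value is
#'     `NONE`, replace it with the previous year's treatment with probability
#'     `mix_probability` (default 0.5).}
#' }
#'
#' `history_semantics` controls which previous-year value the consecutive-year
#' rules of scenarios 1-2 consult: `"assigned"` (the default; the post-policy
#' value, so alternating-year care remains possible) or `"natural"` (the
#' observed value). Scenario 3 always consults the natural history.
#'
#' @param id One of `"identity"`, `"scenario1"`, `"scenario2"`, `"scenario3"`.
#' @param history_semantics `"assigned"` or `"natural"` (scenarios 1-2 only).
#' @param mix_probability Replacement probability for scenario 3.
#' @param rng_seed Seed for scenario 3's randomisation; required when
#'   `apply_policy()` is called without an explicit seed.
#' @return An object of class `policy_spec`.
#' @examples
#' sp <- policy_spec("scenario1")
#' apply_policy(matrix(c("SUB", "SUB", "NONE", "SUPRA"), 1), sp)
#' @export
policy_spec <- function(id = c("identity", "scenario1", "scenario2", "scenario3"),
                        history_semantics = c("assigned", "natural"),
                        mix_probability = 0.5,
                        rng_seed = NULL) {
  id <- match.arg(id)
  history_semantics <- match.arg(history_semantics)
  if (!is.numeric(mix_probability) || mix_probability < 0 || mix_probability > 1) {
    stop_config("mix_probability", "must be in [0, 1]")
  }
  structure(
    list(id = id, history_semantics = history_semantics,
         mix_probability = mix_probability, rng_seed = rng_seed),
    class = "policy_spec"
  )
}

#' @export
print.policy_spec <- function(x, ...) {
  cat("<policy_spec>", x$id,
      if (x$id %in% c("scenario1", "scenario2")) {
        paste0("(", x$history_semantics, "-history semantics)")
      } else if (x$id == "scenario3") {
        sprintf("(mix_probability = %g)", x$mix_probability)
      } else "",
      "\n")
  invisible(x)
}

check_treatment_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  v <- as.vector(x)
  if (!all(v[!is.na(v)] %in% treatment_levels())) {
    bad <- setdiff(unique(v[!is.na(v)]), treatment_levels())
    stop(sprintf("invalid treatment level(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  x
}

# One year of a policy, vectorised over persons. Used both by apply_policy()
# and by the generator when simulating under an intervened treatment process.
#   natural:  this year's natural (observed) value
#   prev_assigned / prev_natural: previous year's values (NA in the first year)
#   u: uniform draws for scenario 3 randomisation
policy_step <- function(spec, natural, prev_assigned, prev_natural, u = NULL) {
  assigned <- natural
  if (spec$id == "identity" || all(is.na(prev_natural))) return(assigned)
  prev_ref <- if (spec$history_semantics == "assigned") prev_assigned else prev_natural
  ok <- !is.na(natural) & !is.na(prev_ref)
  if (spec$id == "scenario1") {
    hit <- ok & prev_ref != "NONE" & natural != "NONE"
    assigned[hit] <- "NONE"
  } else if (spec$id == "scenario2") {
    hit <- ok & prev_ref == "SUPRA" & natural == "SUPRA"
    assigned[hit] <- "NONE"
  } else if (spec$id == "scenario3") {
    if (is.null(u)) stop("scenario3 requires randomisation draws", call. = FALSE)
    eligible <- !is.na(natural) & !is.na(prev_natural) &
      prev_natural != "NONE" & natural == "NONE"
    take <- eligible & u < spec$mix_probability
    assigned[take] <- prev_natural[take]
  }
  assigned
}

#' Apply a modified treatment policy to a treatment-history matrix
#'
#' Processes each person's history left to right, applying the policy rule of
#' [policy_spec()] year by year. Scenario 3 draws its per-person-year
#' randomisation from `seed` (or `spec$rng_seed`).
#'
#' @param observed Character matrix (persons x years) of [treatment_levels()],
#'   or a vector for a single person.
#' @param spec A [policy_spec()].
#' @param seed Seed for scenario 3's randomisation; overrides `spec$rng_seed`.
#' @return Character matrix of assigned treatments, same shape as `observed`.
#' @export
apply_policy <- function(observed, spec, seed = NULL) {
  stopifnot(inherits(spec, "policy_spec"))
  vec_in <- is.null(dim(observed))
  x <- check_treatment_matrix(observed)
  n <- nrow(x); tau <- ncol(x)
  if (tau == 0L || n == 0L) return(observed)
  u <- NULL
  if (spec$id == "scenario3") {
    seed <- seed %||% spec$rng_seed
    if (is.null(seed)) {
      stop_config("rng_seed", "scenario3 requires a randomisation seed")
    }
    u <- with_seed(sub_seed(seed, "scenario3"),
                   matrix(stats::runif(n * tau), n, tau))
  }
  assigned <- x
  for (t in seq_len(tau)) {
    prev_nat <- if (t == 1L) rep(NA_character_, n) else x[, t - 1L]
    prev_asg <- if (t == 1L) rep(NA_character_, n) else assigned[, t - 1L]
    assigned[, t] <- policy_step(spec, x[, t], prev_asg, prev_nat,
                                 u = if (is.null(u)) NULL else u[, t])
  }
  if (vec_in) drop(assigned) else assigned
}

#' Person-years with any periodontal therapy
#'
#' Counts, per person, the years with treatment other than `NONE`, and returns
#' the cohort mean and standard deviation (population convention, divisor n).
#'
#' @param x Treatment-history matrix (persons x years).
#' @return List with `per_person` (integer vector), `mean` and `sd`.
#' @export
person_years_with_therapy <- function(x) {
  x <- check_treatment_matrix(x)
  cnt <- as.integer(rowSums(x != "NONE"))
  n <- length(cnt)
  m <- if (n) mean(cnt) else NA_real_
  s <- if (n) sqrt(mean((cnt - m)^2)) else NA_real_
  list(per_person = cnt, mean = m, sd = s)
}
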