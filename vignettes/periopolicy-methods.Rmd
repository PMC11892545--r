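---
title: "Modified treatment policies for periodontal care: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modified treatment policies for periodontal care: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periopolicy)
```

## The scientific question

Supportive periodontal care is widely delivered on an annual (or more
frequent) schedule, at considerable public cost. A natural policy question
is counterfactual: *if the receipt of subsidised periodontal therapy were
restricted to no more than once every second year, how would the ten-year
risk of losing a tooth change?* The exposure of interest is a three-level
yearly variable — subgingival or surgical periodontal treatment (`SUB`),
only supragingival treatment (`SUPRA`), or none — and the outcome is the
first non-surgical tooth extraction, an absorbing event observed annually.

Because a person's yearly income, diabetes status and dental-service use
both respond to past periodontal care and influence future care and tooth
loss, the data exhibit treatment–confounder feedback: these covariates are
simultaneously confounders and mediators, and conditioning on them in a
single regression is both necessary and wrong. The longitudinal modified
treatment policy (LMTP) framework resolves this by defining interventions as
*transformations of the naturally occurring treatment* and estimating the
counterfactual cumulative incidence with sequential methods that adjust for
time-varying confounding year by year.

## The policies

All policies are explicit maps applied to a person's yearly treatment
history, processed left to right (`apply_policy()`):

* **identity** — the observed pattern (the reference curve);
* **scenario 1** — no periodontal care of any kind in two consecutive
  years: if the previous year (post-policy) was treated and the current
  observed year is treated, assign `NONE`;
* **scenario 2** — no supragingival-only care in two consecutive years;
  `SUB` years are never altered;
* **scenario 3** — an *extension* policy: where a treated year is followed
  by an untreated one in the natural history, the untreated year is
  replaced, with probability 0.5, by the previous year's treatment.

For scenarios 1–2 the consecutive-year rule consults the **assigned**
(post-policy) previous year, so alternating-year care remains possible;
this matches a rule of the form "no more than once every second year" and
reproduces the reported reductions in treated person-years (about 40% and
20–30%) far better than a natural-history rule, which would annihilate any
long run of treated years entirely. The semantics are switchable
(`history_semantics = "natural"`) for sensitivity analysis. Scenario 3
consults the natural history by construction, and its randomisation is
integrated out exactly in the enumeration oracle and by fresh draws in
simulation. The first year has no predecessor and is always kept.

## The estimand and the estimator

For a policy $d$ and horizon $k$, the target is the counterfactual
cumulative incidence $\psi_k^d = P(Y_{k+1}^d = 1)$ of at least one
non-surgical extraction by year $k+1$ had treatment been assigned by $d$
each year, with loss to follow-up (death or emigration) removed — censoring
is adjusted away, not treated as a competing event. Each horizon is
estimated independently, using only the event status at that horizon; the
curves are reported per year with no smoothing across horizons.

The workhorse is the sequentially doubly robust (SDR) estimator. Writing
$H_t$ for the history (baseline block, all pre-treatment covariates through
$t$, post-treatment covariates and treatments before $t$) and $r_t$ for the
density ratio of policy-assigned to natural treatment given history —
multiplied by the censoring factor
$\mathbf{1}\{O_{t+1}=1\}/\hat{P}(O_{t+1}=1 \mid H_t, A_t)$ — the recursion
starts from $V_{k+1} = Y_{k+1}$ and, for $t = k, \dots, 1$:

1. regress $V_{t+1}$ on $(H_t, A_t)$ among at-risk, observed persons to
   obtain $\hat{Q}_t$ (a super learner);
2. set $V_t = \hat{Q}_t(H_t, A^d_t) + r_t\,(V_{t+1} - \hat{Q}_t(H_t, A_t))$,

with $V_t = 1$ carried deterministically for persons whose event precedes
$t$ (they are excluded from nuisance fitting). The estimate is
$\hat\psi = \bar{V_1}$ with standard error $sd(V_1)/\sqrt{n}$ — the
influence-function variance — and Wald 95% intervals. The per-step ratio
(not a cumulative product) multiplies the residual; products arise through
the nesting. The estimator is consistent if, at every time point, either
the ratio or the outcome regression is consistent.

Two cross-checks ship alongside: iterated-regression g-computation (the
recursion without the residual term; point estimate only) and an IPW
estimator using cumulative ratio products frozen at the event. On an
exactly enumerable validation process all three converge to the same truth
(`tests/testthat/test-estimators.R`).

Density ratios are estimated by the classification trick: each at-risk
person contributes two stacked records with identical history, one with the
natural treatment (label 0), one with the policy-assigned treatment
(label 1); the cross-fitted classifier's odds at the natural record estimate
$r_t$. Two implementation details matter in practice:

* **Policy-structure features.** The scenario rules make the ratio's
  dependence on history live inside specific (previous assigned treatment
  × current treatment) cells. The classifier therefore receives, besides
  main effects, the assigned-previous-treatment dummies and their
  interactions with the current treatment and with a small set of history
  drivers (cumulative treated-year rate and the current income/diabetes
  block). Without these, no main-effects learner can represent the ratio;
  with them, even a plain ridge regression is close to well-specified.
* **Stabilization.** The true ratio has conditional mean 1, so each year's
  estimated ratios are normalised to mean 1 over the at-risk set
  (`stabilize_ratios = TRUE`). This removes multiplicative estimation drift
  that otherwise compounds across ten years (we observed the IPW
  cross-check move by several percentage points without it) and changes
  nothing asymptotically. Ratio truncation is off by default — weights are
  checked (positivity diagnostics report the maximum and 99th percentile of
  cumulative products per horizon, with a configurable warning threshold),
  not truncated; an optional quantile cap is available in
  `lmtp_control()`.

Cross-fitting uses 5 folds: nuisances are trained on the fold complement,
pseudo-outcomes are propagated within training data using training-fitted
predictions, and the evaluation-fold scores are pooled. Super-learner
cross-validation defaults to 2 folds for treatment/ratio and censoring
models and 10 folds for the outcome regressions.

## The super learner

Every nuisance is fitted with a stacked ensemble (`fit_superlearner()`):
candidates are cross-validated, convex weights minimising the
cross-validated squared-error risk are found by non-negative least squares
on the simplex (then normalised; if stacking would lose to the best single
candidate the weights fall back to that vertex), and candidates are refitted
on all data. The default candidate set is a ridge-regularised GLM (the
Gaussian-prior MAP version of a Bayesian GLM — identical point predictions
with no sampler), an L1-penalised GLM, and a random forest. Penalties are
chosen on an internal grid by the ensemble's own folds; random-forest
defaults (200 trees, unrestricted depth) are exposed as hyperparameters.
Squared error was chosen as the stacking loss (the loss is switchable in
spirit by replacing the weight solver; candidates themselves use their
natural likelihoods). Additional single-purpose families are available for
validation work: an unpenalised GLM, a quasibinomial GLM for fractional
labels, a saturated cell-means learner for discrete processes, and an
intercept-only learner used in the double-robustness experiments.

Binary-task predictions are clipped to $[10^{-6}, 1-10^{-6}]$.
Continuous-task predictions are clipped to the training-label range:
sequential pseudo-outcomes legitimately leave $[0,1]$, so clipping to the
unit interval would bias the recursion, while clipping to the label range
is inert when labels are proper probabilities. The quasibinomial family
maps labels affinely into $[0,1]$ before fitting and inverts the map at
prediction time for the same reason.

## The synthetic registry generator

Real Danish register extracts are access-restricted, so the package ships a
generator (`simulate_cohort()`) that emulates the *statistical structure*
of such a cohort: 20 000 fifty-year-olds followed 2011–2021, with

* baseline demographics drawn from the published 2011 cross-section
  (sex, origin, six education levels with unknown attainment pooled into
  "other", six region groups);
* 1990–2010 service-history summaries: years-with-service counts as
  overdispersed binomials (person-level Beta propensities over 21 years),
  negative-binomial restoration and extraction totals, and an
  income-percentile sum tied to the person's income level;
* yearly income percentile evolving as a reflected bounded random walk on
  [0, 100] with a slight negative drift (preserving percentile semantics),
  and an absorbing diabetes flag with income-dependent onset;
* a three-level treatment process whose any-therapy logit combines a
  person-level propensity (shared with the service history), the previous
  year's treatment, income, diabetes and lagged oral-examination status —
  the treatment–confounder feedback loop — with a SUB-vs-SUPRA split driven
  by subgingival history;
* post-treatment service covariates (examination, prevention, radiographs,
  endodontics, restorations) responding to same-year treatment and entering
  the treatment model only with a one-year lag;
* a yearly event hazard that is logistic-linear in observed covariates
  (extraction history, income, diabetes, education, lagged examination)
  plus `theta_treat` log-odds per recent treated year — **zero by default**,
  so policy contrasts are null by design up to a small indirect
  examination channel (about +0.2 points at ten years for scenario 1);
* informative censoring at each year end, logistic in income, diabetes and
  sex, with the censored person contributing the full current year
  (matching a cross-section of survivors reported at the end of follow-up).

Within a year the generation order is L → X → W → next-year event →
censoring. All unobserved person-level propensities enter only the
treatment and service models, so exchangeability holds by construction at
`confounding_dial = 0`; the dial adds a shared frailty to both the
treatment and outcome logits to emulate unmeasured confounding (standing in
for smoking, which registries do not record).

Default parameters were calibrated once, by simulation at n = 20 000,
against the published marginals: 50% men, 95% Danish origin, diabetes
3.8% → 8.0%, oral examination 67% → 62%, prevention 7.9% → 22%, 5.9% lost
to follow-up, 25.1% ten-year incidence, and a mean of 6.2 treated years
over the ten exposure years. Under the three policies the generated
treated-year means (≈3.9 / ≈4.9 / ≈7.1 against observed ≈6.2) fall within
15% of the reported counterfactual reductions and extension.

One deliberate departure from the printed table: the reported
between-person spread of treated years (SD 3.6) can only be reproduced by
making yearly attendance nearly deterministic for a sizeable group. That
would place essentially zero probability on the treatment values the
restriction policies assign — a *practical positivity violation* — whereas
the published analysis explicitly checked its weights and found them
acceptable. We therefore bound the yearly any-therapy probability to
[0.02, 0.78] (even the most regular attenders occasionally skip a year) and
obtain the spread from persistence plus moderate heterogeneity, accepting a
smaller SD (≈2.0) in exchange for a cohort on which the estimand the paper
reports is actually identifiable with stable weights. The bound is a config
parameter (`treatment_model$p_bounds`) and can be relaxed to study the
estimator under strained positivity.

## Ground truth and validation design

Two oracles anchor all validation. `truth_by_simulation()` re-runs the
generator with treatment assigned by the policy each year (downstream
covariates responding to the assigned value) and censoring disabled.
`truth_by_enumeration()` computes exact trajectory sums for a small binary
process with treatment–confounder feedback (`tiny_dgp_config()`),
integrating scenario 3's randomisation exactly; simulation and enumeration
agree within Monte-Carlo error, and enumeration values for degenerate
policies were verified by hand.

The validation studies in `tests/testthat/test-acceptance.R` use problem
sizes chosen to keep the full suite within a desk-scale run:

* oracle agreement at n = 50 000 on the enumerable process (tolerance
  0.01–0.015);
* 95% CI coverage over 100 replicates of a scaled-down cohort (n = 2000,
  five treatment years, protective effect −0.15 log-odds, moderated
  propensity spread so positivity comfortably holds) — coverage must land
  in [90%, 98%] with absolute bias below one percentage point;
* double robustness on the enumerable process at n = 20 000: intercept-only
  outcome regressions with saturated ratios, and degenerate (constant-1)
  ratios with saturated regressions, each within one point of truth;
* the null-effect study at n = 20 000 over all ten horizons and all three
  scenarios, requiring every risk difference against the observed pattern
  to stay within one percentage point.

The generator emulates marginals, feedback structure and informative
censoring, but not everything about real registries: no within-year visit
timing, no municipality-level clustering, no tooth-level states, no
competing mortality risk (death is censoring, as in the analysis being
emulated), and service co-occurrence beyond the shared propensities is not
modelled. Passing tests therefore demonstrate the *methodology* —
calibration, policy mechanics, estimator correctness, coverage — not
agreement with the restricted real data.

## Numerical choices and degenerate inputs

* Estimated observation probabilities are floored at 0.01 (no censoring
  factor exceeds 100); binary classifier probabilities at $10^{-6}$.
* Single-class labels yield a degenerate constant learner with a recorded
  note; binary fits with fewer than three observations in a class fall back
  to the constant (a penalised fit on one event is noise).
* When a policy leaves every treatment unchanged (the identity, or
  scenario 2 on a cohort without supragingival-only years) the stacked
  classifier's records are duplicated with opposite labels; these ratios
  are set to 1 directly and the shortcut is logged.
* An empty cohort keeps the full panel schema with zero rows; summaries
  flag proportions as undefined rather than returning 0/0.
* Ties in the NNLS stack (all-zero weights) fall back to the best single
  candidate.
* One master seed drives everything; sub-seeds are derived per stream
  (cohort, folds, each nuisance fit, policy randomisation) so modules are
  independently reproducible and row-permutation with carried fold labels
  leaves results unchanged.

## Known limitations

Scenario 1 at the ten-year horizon remains the statistically hardest cell:
even with bounded attendance probabilities its cumulative weights reach the
hundreds for rare alternating histories, and the SDR risk-difference
standard error at n = 20 000 is ~0.5–0.7 percentage points there, several
times wider than at earlier horizons. G-computation/IPW are point
cross-checks without variance, by design. The delta-method risk-ratio
interval is asymptotic and can be unstable when the reference incidence is
very small. No targeted (TMLE) variant, continuous-time survival, or
competing-risk estimand is provided.
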