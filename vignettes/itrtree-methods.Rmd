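---
title: "Estimating individualized treatment rules for traumatic finger amputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individualized treatment rules for traumatic finger amputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itrtree)
```

## The decision problem

A patient presenting with a traumatic finger amputation can be treated by
replantation (surgical reattachment of the digit) or revision amputation
(primary closure of the stump).  Neither arm dominates: long-term hand
strength, dexterity, pain, and patient-reported quality of life trade off
differently depending on the injury.  `itrtree` estimates an
*individualized treatment rule* (ITR) — a shallow decision tree over
clinically interpretable tailoring covariates that maps each patient to the
arm with the better expected long-term outcome — from observational cohort
data, where treatment assignment is confounded by site practice patterns
and injury characteristics.

The method is tree-based reinforcement learning (T-RL) applied to a
single-stage treatment decision: recursive partitioning in which the split
criterion is not a prediction-error purity but the *estimated
counterfactual mean outcome* the node's patients would attain under their
best node-level treatment assignment.

## Composite outcomes

Raw outcomes are bilateral: each functional measure is recorded for the
injured and the healthy hand, so each patient serves as their own control.
Four composites are built, all oriented so larger is better:

* **strength** — for grip, lateral pinch, 2-point pinch and 3-point pinch,
  form the injured-minus-healthy difference `d`, standardize each `d` to a
  z-score over the analysis cohort, and average the four z-scores;
* **dexterity** — standardized healthy-minus-injured 9-hole peg time (a
  slower injured hand gives a negative difference);
* **pain** — standardized healthy-minus-injured pain (0-100); the construct
  assumes the healthy hand hurts no more than the injured one, so positive
  differences are truncated to zero (default) or the record dropped
  (`violation = "drop"`), with violations always flagged in the component
  log;
* **quality of life** — mean of standardized MHQ and standardized reversed
  DASH (100 − DASH).

Differences are formed first and standardized second, matching the stated
construction order.  Standardization uses the sample SD (n − 1) over the
analysis cohort itself — the complete cases for the outcome at hand —
computed once before tree search; there is no external reference
population.  Each standardized component therefore has mean 0 and SD 1 by
construction, and every composite is invariant to shifting both hands'
measures by a constant and to rescaling a measure's units.

## Propensity score and balance

P(A = replantation | X) is estimated with a small stacked ensemble in the
SuperLearner spirit: intercept-only, main-effects logistic regression, a
single classification tree (`rpart`), and a probability random forest
(`ranger`).  All measured baseline covariates enter — candidates and
socio-economic confounders — with no a priori selection, one-hot encoded
with first-level reference so that every learner sees the same fixed
numeric design.  Stacking weights minimize the 10-fold cross-validated
Brier score over the simplex, solved by non-negative least squares followed
by normalization (the standard NNLS convention); the Brier score is a
proper, convex loss that stays finite under probability clipping, which
log-loss does not.  Folds are stratified by arm and assigned
deterministically in a canonical covariate ordering, which makes fitted
probabilities invariant to the caller's row order.  Predictions are
truncated to [0.01, 0.99] because the cohort exhibits limited overlap (site
strongly predicts treatment) and untruncated inverse weights destabilize
everything downstream.  The probability forest uses generous terminal
nodes (`min.node.size = n/50`): deep leaves give poorly calibrated
probabilities, and inverse weighting amplifies calibration error.

`balance_report()` computes absolute standardized mean differences (ASMD)
per covariate term — continuous terms standardized by the pooled unadjusted
SD, binary terms and factor-level indicators by `sqrt(p(1-p))` at the
pooled proportion — unadjusted and weighted by the inverse propensity of
the received treatment (Hájek-normalized within arm), flagging terms above
the conventional 0.1 threshold, plus per-arm propensity quantiles for
overlap.

## Doubly robust pseudo-outcomes and the tree search

With per-arm conditional-mean models m(X, a) (random forest by default,
main-effects linear as the documented alternative), the AIPW pseudo-outcome
for patient i and arm a is

    psi[i, a] = 1{A_i = a} / pi_a(X_i) * (Y_i − m(X_i, a)) + m(X_i, a)

whose column means are consistent for E[Y(a)] if *either* nuisance is
correctly specified.  Nuisances are fit once on the analysis cohort
(no cross-fitting), mirroring the single-stage application; the estimated
value of any assignment rule g is the mean of `psi[i, g(X_i)]`.

`grow_tree()` searches depth ≤ 2 trees over the analysis's candidate
tailoring covariates.  At each node, candidate splits are thresholds at
midpoints of consecutive distinct observed values (numeric and ordinal
covariates; logicals as 0/1), or level subsets up to complementation
(nominal mechanism of injury: 3 splits).  A split's purity is the
size-weighted sum of its children's best-single-action mean pseudo-
outcomes; the implementation scores every threshold of a numeric covariate
in one cumulative-sum pass, so n = 8000 cohorts search in seconds.  Ties
break deterministically: earlier covariate in the candidate list, then
smaller threshold, and single-action ties go to replantation.

**The 5% minimum-improvement rule.**  The stopping configuration is a
maximum depth of 2 and a minimum 5% improvement in the purity measure for a
new split.  "5% of what" is a genuine design choice on z-scored outcomes
whose node purity can sit arbitrarily close to zero: the default accepts a
split iff `purity(split) − purity(no split) ≥ λ·|purity(no split)|` with
λ = 0.05, and falls back to an absolute criterion `λ·sd(psi in node)`
whenever `|purity(no split)| < 0.1·sd(psi in node)` — otherwise a
near-zero baseline purity would admit every split (or, approaching from
below, none).  Both constants are exposed in `trl_control()`.  Child
actions during split scoring are unrestricted (the two children may share
an action); `min_node_size = 20` keeps leaf-level pseudo-outcome means from
being dominated by single inverse-weighted observations.

## The synthetic cohort generator

The motivating multinational cohort is not publicly deposited, so the
package ships a generator whose defaults *are* the study conditions every
validation experiment runs under, calibrated to the published summary
table:

* age truncated normal on [18, 82] with SD 16, latent mean solved
  numerically so the truncated mean is 45; 84% male; 14.6% US site; number
  of fingers amputated on {1..5} with probabilities (.55, .25, .12, .05,
  .03) giving median 1 and IQR [1, 2]; 25% thumb involvement; mechanism
  mix 40/15/45 clean-cut/avulsion/crush; 40% dominant-hand injury; 62%
  distal amputations; 5% bilateral.
* site, race/ethnicity and work-related injury are generated with strong
  pairwise association (the cohort's documented confounding pathology);
  all other covariates are independent — the source reports only
  marginals, so any further covariance would be invention.
* treatment follows a logistic model in site, mechanism, finger count, age
  and thumb involvement, with coefficients chosen to reproduce the
  published per-arm compositions (28% vs 9% US share, 24% vs 47%
  clean-cut, arm age gap ≈ 5 y) and the intercept calibrated by
  Monte-Carlo so the expected replantation share is 131/185.
* healthy-hand measures are drawn first; injured-hand measures equal the
  healthy measure times a treatment- and covariate-dependent recovery
  fraction plus noise shared across arms, so the per-patient arm contrast
  is exact and each composite's conditional arm contrast changes sign
  precisely across the configured true rule's leaves.  Default true rules:
  strength — revision iff one finger and age ≤ 42; quality of life —
  revision iff dominant hand injured; dexterity and pain — replantation
  for all.  `effect_size = "strong"` scales the interactions up for
  rule-recovery experiments; `pain_violation_prob` injects
  healthy-worse-than-injured pain records to exercise the truncation rule.
* missingness is missing-at-random by assessment block (strength,
  dexterity, pain, QOL instruments go missing together, as whole
  assessments do in practice), with probability depending on site and age;
  block intercepts are calibrated so a 338-patient cohort retains about
  185 default complete cases.  Two socio-economic covariates get small
  completely-at-random missingness so covariate imputation is exercised.

Both potential outcomes are retained as an attribute, giving every
downstream experiment exact ground truth; `oracle_optimal_rule()` verifies
by brute-force Monte-Carlo (default 100 000 patients) that the declared
rule is beaten by no single action, no single split, and no random
comparator rule beyond two Monte-Carlo standard errors.

What the generator does **not** emulate: inter-site clustering beyond the
site covariate, longitudinal recovery trajectories, item-level MHQ/DASH
scoring, informative (missing-not-at-random) dropout, and surgeon
expertise.  Passing recovery experiments therefore show the estimation
machinery is sound under realistic confounding, limited overlap and MAR
missingness — not that any particular published rule is clinically
correct.

## Imputation

For the full-cohort sensitivity analysis, `rf_impute()` performs
missForest-style single imputation: mean/mode initialization, variables
revisited in increasing-missingness order, each regressed on all others
with a random forest fit on its originally observed rows, sweeps stopping
when the divergence criterion (normalized squared change for numerics plus
disagreement fraction for categoricals) first rises.  Observed cells are
never altered; imputed values are clipped to their schema domains.
Outcomes and covariates are imputed jointly in one sweep.  No multiple
imputation: the downstream analysis consumes a single completed cohort.

## Numerical and design choices

* Complete cases for an analysis are records observed on the candidate
  covariates, the propensity confounders, and the raw measures of the
  outcome being analyzed (the published analysis does not state its
  definition; this is the least restrictive set that lets every stage
  run).
* The descriptive summary chooses t-test/mean(SD) versus
  Wilcoxon/median(IQR) by a deterministic rule — pooled |skewness| < 1 —
  and uses the upper-tail Pearson chi-square without continuity correction
  for categoricals.
* Problem sizes for the packaged validation experiments: marginal
  calibration averages 200 cohorts of n = 185; the complete-case rate
  averages 200 cohorts of n = 338; balance is checked at n = 2000 with the
  correctly specified (intercept + logistic) stack — the condition the
  property is about, since adding tree/forest learners makes the fitted
  score deliberately *mis*-specified; double robustness at n = 4000;
  rule recovery over 100 cohorts of n = 2000 with fast nuisances
  (intercept/logistic/tree stack, linear outcome model — AIPW needs only
  one correct nuisance) and once at n = 8000 with the full default
  pipeline.
* Known limitations: no cross-validated depth selection or pruning beyond
  the fixed depth-2 / 5% configuration; no multi-stage (dynamic) regimes;
  the rendered sentences cover depth ≤ 2 trees, deeper trees print as
  condition lists; inference (confidence intervals for rule values) is out
  of scope.
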