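---
title: "A one-step Q-learning policy for EGFR TKI treatment selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A one-step Q-learning policy for EGFR TKI treatment selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkipolicy)
```

## The decision problem

For advanced non-small cell lung cancer with an activating EGFR mutation,
the first tyrosine kinase inhibitor (TKI) can be given first-line or after
chemotherapy, and can be a first-generation drug (erlotinib, gefitinib) or
a second-or-higher-generation one (afatinib, dacomitinib, osimertinib).
Crossing the two dichotomies yields a four-level action variable, and the
clinically relevant outcome here is dichotomous: was the patient
progression-free one year after starting the TKI?

`tkipolicy` learns a per-patient valuation of the four actions from a
retrospective table of such decisions and outcomes. The package contains
the whole path from raw table to recommendation: inclusion filtering,
feature engineering, class balancing, a supervised feature screen, the
reinforcement-learning policy itself, and reporting.

## One-step episodes: why a contextual bandit

The data record exactly one treatment decision per patient — there are no
observed state transitions. The environment is therefore episodic with
horizon one: an episode samples a patient uniformly, the agent selects an
action, receives a reward, and the episode terminates. For terminal
one-step episodes the Q-learning target `r + γ max Q_target(s', ·)`
degenerates to the immediate reward, so the discount `γ` is inert and the
network's fixed point is the conditional mean reward `E[r | s, a]`. We keep
the full DQN machinery (replay buffer of 10,000, minibatch 32, target
network synchronized every 500 steps, Adam at 1e-3, 50,000 timesteps)
because it is the standard, well-understood trainer for this objective and
keeps the implementation honest against the more general contract; the
architecture is a multi-layer perceptron with two hidden layers of 64 ReLU
units and four linear outputs, on standardized features.

Exploration is Boltzmann: actions are drawn with probability proportional
to `exp(Q/τ)`. The temperature `τ` (default 1, in reward units) matters
mostly for coverage of the counterfactual actions; the defaults visit every
unmasked action thousands of times at the default problem size. The softmax
is computed with max-subtraction, so masked actions can be encoded as
`-Inf` and arbitrarily large Q-values do not overflow.

## Reward shaping

The reward table (`reward_config()`) is the scientific heart of the policy
and also its most assumption-laden part:

* recorded action, progression-free at 1 year: `match_good = 15`;
* recorded action, progression/death before 1 year: `match_bad = 10`;
* any other action: `mismatch = 12`;
* actions 1 and 3 (higher-generation TKI): `+ generation_bonus = 1`.

The constraint `match_good > match_bad` is structural — a progression-free
year must be preferred. The **off-policy gap** deserves emphasis: when the
agent proposes an action the patient did not receive, the data say nothing
about the counterfactual outcome. We assign a neutral constant between the
two matched rewards, which makes `E[r | s, a]` for a mismatched action
independent of outcome and pulls the learned policy toward actions whose
*recorded* outcomes were good in similar patients. Any counterfactual model
can replace this via the `reward_fn` hook on `treatment_env()`. The
generation bonus encodes the trial-level prior that higher-generation TKIs
extend progression-free survival; its default (1, about one fifth of the
match spread) nudges ties rather than overriding observed outcomes, and the
test suite verifies monotonicity: raising it never lowers the policy's use
of higher-generation actions.

The magnitudes (teens) are arbitrary units; only differences matter.
Reported Q summaries inherit the scale of whatever table is configured.

Treatment line is handled by **scenario branching**. The default
`"masked"` mode makes line-inconsistent actions unavailable (first-line
patients choose between actions 0/1, later-line between 2/3), mirroring
the clinical reality that the line is context, not choice, at decision
time. The `"penalized"` alternative leaves all four actions available and
subtracts `line_inconsistency_penalty` instead; with the penalty set to 0
it is also the configuration under which all sixteen (stratum, action)
values can be audited against enumeration.

## Feature engineering and cohort statistics

* Natural logarithms for both transformed features (`lognlr`, `logage`);
  only the base's scale differs between log conventions, and the natural
  log is the modelling default.
* The progression category dichotomizes PFS at twelve months with an
  **inclusive** boundary (12.0 months counts as progression-free: "a year
  or more").
* Inclusion rules: at least one month of follow-up, and records without an
  event inside the first year must have at least twelve months of
  follow-up, otherwise the endpoint is undefined for them. Filtering
  partitions the input exactly and logs the first failing rule per row.
* The NLR comparison across progression groups is a pooled-variance
  (Student) two-sample t-test with `df = n1 + n2 - 2`; with groups of 196
  and 122 this gives the characteristic 316 degrees of freedom.
* Descriptive summaries report counts with percentages at one decimal, and
  mean/sd/median/min/max for numeric variables.

## Class balancing and the screen

The progression classes are imbalanced (roughly 60/40 toward early
progression), so before supervised screening the minority class is
oversampled by SMOTE: each synthetic point lies uniformly on the segment
between a minority point and one of its `k = 5` nearest minority neighbors
(`k` is the technique's canonical default; the neighbor search runs on
standardized coordinates, the interpolation on the original scale). One-hot
columns are rounded back to {0, 1} after interpolation, a pragmatic
handling of categorical features inside an interpolation-based method.
Balancing runs on the full table **before** the 90/10 modeling split —
deliberately matching the analysis pipeline this package mirrors, although
it leaks synthetic neighbors across the split; `train_eval_split()` can be
called first when a leakage-free protocol is preferred. The split uses
largest-remainder apportionment so the training size is exactly
`round(0.9 n)` while stratum shares stay within one unit of the target.

The screening classifier is an ensemble of extremely randomized trees
(100 trees, Gini impurity, no bootstrap, random split thresholds), fitted
through `ranger`; importances are normalized mean impurity decrease.
Metrics come from stratified 10-fold cross-validation (the fold count is
the common tabular-ML default). The constant dummy baseline pins the
metric floor: tied scores give AUC exactly 0.5, recall 1, kappa and
Matthews correlation 0. Only these two models are provided; a broader
model zoo is a screening nicety, not part of the method.

## The synthetic cohort generator

No patient-level data ship with the package. `generate_cohort()` draws a
cohort whose *marginals* match a published multicenter EGFR-mutant NSCLC
cohort of 318 patients: age 62.7 ± 11.4 years, 52.2% female, 16.7% ECOG
2–4, 64.2% Exon 19 deletions, 36.8% current smokers, 53.5% with four or
more metastatic sites, 56.9% bone/liver and 37.1% brain metastases, a
log-normal NLR targeting mean 3.9 and median 3.2, and an action
distribution of 63.5 / 14.8 / 4.7 / 17.0 percent over codes 0–3.
Comorbidity prevalence is not reported for that cohort; 30% is used as
typical for advanced NSCLC. Neutrophil and lymphocyte counts are
back-solved from the sampled NLR and a log-normal lymphocyte draw
(median 1800/µL), since only the ratio's distribution is known.

Outcomes are **planted**: a configurable `effect_table` gives
P(progression-free ≥ 12 months) per (stratum × action), with strata
defaulting to mutation × line. The default table gives
second-or-higher-generation actions a moderate advantage (e.g. 0.40 vs
0.52 for actions 0 vs 1 in first-line Exon 19 patients) and lands the
cohort-wide progression-free share near the published 38%. The planted
argmax (`planted_policy()`, ties to the lowest code) is the oracle for
policy-recovery tests. Administrative censoring truncates 8% of follow-up
times after the outcome draw, so the inclusion filters have real work to
do.

What the generator does **not** emulate: joint correlations among clinical
features (only marginals are specified), calendar-time effects, center
effects, and any real biology linking features to outcomes beyond the
effect table. Passing tests on this cohort therefore demonstrate that the
pipeline recovers structure that is present, not that such structure exists
in real data.

## Numerical and reproducibility choices

* All stochastic components draw from R's seeded generator; identical
  configuration and seed give bit-identical cohorts, SMOTE outputs, folds,
  and trained networks (single-threaded `ranger`, plain-R training loop).
* Standardization drops zero-variance columns, records them on the scaler,
  and the stored scaler is reapplied verbatim at inference; records more
  than 5 standard deviations outside the training range are scored with a
  warning.
* Greedy argmax ties break toward the lowest action code, everywhere.
* The policy AUC is this package's own construction (no canonical AUC
  exists for an RL recommender): each patient is scored by the fitted Q at
  the treatment actually received, and that score is ranked against the
  progression-free-year outcome. On training data this saturates toward 1
  as the network capacity lets matched rewards be fitted per patient; it is
  a comparison device, not a validation estimate — use a holdout via
  `policy_score_auc(fit, newdata)`.
* Test problem sizes: convergence of the learned Q to enumerated mean
  rewards is checked on a four-stratum discrete fixture at the full 50,000
  training timesteps (tolerance 0.5 reward units); planted-dominance
  recovery averages three seeds at the same length; distributional checks
  on the generator use 10,000–20,000 patients and three-standard-error
  bands. These sizes were chosen to make the checks sharp at routine
  laptop runtimes.

## Limitations

The method inherits every caveat of offline policy learning from
observational data: confounding by indication (treatment choice correlated
with prognosis), the neutral-mismatch counterfactual assumption, and an
endpoint (one-year progression dichotomy) that discards time-to-event
information — survival modelling is intentionally out of scope. The
recommendation is a decision support construct over four coarse action
categories; it does not model toxicity, specific drugs within a
generation, or resistance mutations. None of the package's outputs are
clinical advice.
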