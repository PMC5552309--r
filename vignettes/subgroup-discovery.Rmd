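---
title: "Risk subgroup discovery with weighted classification trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk subgroup discovery with weighted classification trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adversitree)
```

## The model

`adversitree` targets a common design in life-course epidemiology: a survey
cohort of children with per-individual longitudinal weights, a binary
adolescent outcome (here, self-reported suicidal thoughts), six binary
secondary outcomes, and on the order of 75 early-life predictors, each
dichotomized with item non-response folded into the negative level
(*yes* vs *no/missing*). The scientific object is not a risk score but a set
of **high-risk subgroup profiles**: conjunctions of predictor conditions
defining small groups whose outcome prevalence is a large multiple of the
population base rate.

The pipeline is classification-tree based:

- **Growth.** Binary splits of the form `predictor == yes` vs `no/missing`.
  The split criterion is the decrease in Gini impurity `2p(1-p)` computed
  with survey weights (both the node prevalence `p` and the child-size
  mixture weights are weighted). The only stopping rule is a minimum node
  size: a split is admissible when both children contain at least `n_min`
  *unweighted* individuals and the impurity decrease is strictly positive.
  `n_min` is a head count because the rule exists to guarantee estimable
  leaf prevalences, not design-consistent totals; the default 64 is 1% of a
  cohort of 6,388 and should be re-derived as 1% of other cohorts.
- **Risk designation.** With base rate `p0`, the weighted prevalence at the
  root, a node is **high** when its prevalence strictly exceeds `2 p0`,
  **low** when strictly below `p0 / 2`, otherwise **moderate**. Boundary
  prevalences are moderate: the designations are defined with strict
  inequalities, and we keep the boundary case conservative.
- **Pruning.** In post-order, any internal node whose entire subtree — the
  node itself and every descendant, not just the leaves — carries a single
  risk level collapses to a terminal with that level. Because each internal
  node already stores its pooled counts, collapse is exact: pooled weight,
  head count and weighted prevalence are conserved, and every pruned
  terminal is a union of original terminals. Homogeneous-subtree collapses
  are confluent, so the fully pruned tree is unique and minimal in terminal
  count; this is what the test suite verifies exhaustively on small trees.
- **Profiles and classification.** Each high-risk terminal yields a profile:
  its root-to-leaf conditions, training prevalence, and size. A person is
  classified high risk when some profile's conditions all hold. On the
  training cohort the profiles partition the high-risk leaves exactly; on
  other cohorts profiles may overlap, so the first match in
  descending-prevalence order is recorded.
- **Diagnostics.** The high-risk flag is crossed with each outcome in a 2x2
  table kept in weighted and unweighted form. Sensitivity, specificity, PPV
  and NPV are computed on the weighted cells; 95% intervals use the Wald
  normal approximation on the relevant margin's *unweighted* size (Wilson
  offered as an option). A design-effect adjustment would need replicate
  weights, which the pipeline does not consume; the choice is recorded on
  the result object. Zero margins give flagged `NA`s, never silent zeros.
- **Baseline.** Stepwise logistic regression: Wald-p-driven forward entry
  (smallest p below `entry_alpha = 0.05`) followed by backward removal
  (largest p above `stay_alpha = 0.05`), with revisited-state detection to
  guarantee termination. The fitted model classifies by
  `P(outcome) > 0.5` by default; at a 12% base rate few fitted values
  exceed 0.5, which is exactly why a main-effects baseline has poor
  sensitivity — the package also provides `threshold_sweep()` to compare
  classifiers at matched specificity instead of at a fixed threshold.

## The synthetic cohort generator

The motivating microdata are restricted-access, so the generator emulates
their statistical structure rather than their content:

- **Predictors.** A single latent standard-normal "adversity" factor per
  child; predictor `j` is *yes* when
  `sqrt(rho) z + sqrt(1-rho) e_j < qnorm(marginal_j)`. One parameter `rho`
  (`clustering_strength`, default 0.3) reproduces the high co-occurrence of
  early-life adversities; marginals default to an even 0.05–0.50 spread,
  the range typical of dichotomized adversity items. Item missingness is
  drawn per predictor and immediately folded to the negative level,
  mirroring the *no/missing* coding.
- **Weights.** Gamma with mean 1 and coefficient of variation
  `weight_dispersion` (default 0.5): non-negative and right-skewed like
  post-stratification weights, mean 1 so weighted and unweighted sample
  sizes stay comparable.
- **Outcome.** Planted subgroups are conjunctions of predictor conditions
  with a configured within-group prevalence (declared order resolves
  overlap; the bundled example sets are disjoint by construction, like tree
  leaves). Non-members draw at a background rate solved so the overall
  weighted prevalence equals the 12% default; an infeasible configuration
  (background rate outside [0, 1]) is an explicit error.
- **Secondary outcomes.** Each loads on the same latent factor (default
  loading 0.6) plus a membership bump (default 1.0 on the log-odds scale),
  with intercepts calibrated by root finding so each hits its target
  prevalence. Defaults span 11.4%–26.4%, the range reported for adolescent
  adverse outcomes; only the extremes of that range are anchored by
  published figures, the four interior values are this package's choice.
  This shared structure makes the multifinality analysis — one
  classification screening several outcomes — meaningful in simulation.
- **Validation cohort.** A second, independent draw from the same spec
  (seed derived deterministically), observed through a predictor mapping:
  per-variable proxy disagreement flips, unmapped variables absent.
  Membership and outcomes are generated from the *latent* predictors, so
  proxy noise genuinely degrades transported classification.

What the generator does **not** emulate: longitudinal wave structure and
attrition, questionnaire-level content, informative missingness, weights
correlated with risk, and real predictor dependence beyond a single factor.
Passing tests therefore demonstrate the pipeline's correctness and its
behaviour under a plausible dependence structure — not performance claims
about any real cohort.

## Study-scale defaults and problem sizes

The bundled `example_planted_subgroups()` places four disjoint subgroups
(prevalences 0.41, 0.35, 0.30, 0.27 against a 0.12 base) as leaves of a
conceptual tree: a sex-like 50% splitter, then nested conditions on
moderate-marginal predictors — the qualitative architecture reported for
early-adversity trees (a dominant first split, then different branches for
different family constellations). `interaction_planted_subgroups()` reuses
the same few predictors at *opposite* levels across three subgroups, so
marginal effects nearly cancel; these cohorts separate conjunction-capable
classifiers from main-effects logistic regression and drive the
benchmark test.

Test and demonstration runs use cohorts of 3,000–6,388 with `n_min` at 1%,
oracle-equivalence checks at n ≤ 300 with up to 8 predictors, and recovery
studies at n = 20,000 with 75 predictors and `n_min = 200` (again 1%); at
these sizes the full suite runs in about two minutes and recovery of the
planted condition sets is strong (mean Jaccard well above 0.8 in the
acceptance run).

## Numerical choices

- Gini decreases are clipped at zero against floating residue, and split
  candidates within `1e-10` of the maximum are treated as tied, with the tie
  broken by the lowest predictor column position. Complementary partitions
  (two predictors splitting the same node into mirrored halves) are
  mathematically tied but differ in the last float bits; the tolerance makes
  growth reproducible against an independent implementation.
- Node prevalences are always survey-weighted; `use_weights_in_splitting`
  can switch the impurity computation to head counts for sensitivity
  analyses, since reports rarely state which was used.
- The background-rate calibration and the secondary-outcome intercepts are
  solved exactly on the realized draw (weights and memberships), not in
  expectation, so small cohorts still hit their targets on average.
- Stepwise selection refits by `stats::glm` (binomial IRLS) with the
  survey weights as case weights; the usual non-integer-successes warning
  is muffled, while separation warnings are surfaced as a flag on the
  model object.
- The unmapped-condition policy defaults to `never-fires`: a profile with an
  unverifiable condition classifies no one, which cannot create spurious
  high-risk calls. `drop-condition` reproduces the closest-proxy-and-proceed
  behaviour and can only widen a profile's match set; `fail` makes porting
  strict.

## Known limitations

- No surrogate splits, multiway splits, or cost-complexity pruning — the
  pipeline implements the node-size-plus-risk-homogeneity scheme only.
- Confidence intervals ignore the sampling design (no replicate weights);
  weighted point estimates with unweighted-margin intervals are a pragmatic
  compromise, flagged on every result.
- The logistic comparator's classification threshold is a genuine free
  parameter; 0.5 is the canonical default and `threshold_sweep()` exists
  precisely because conclusions at a single threshold are fragile.
- Recovery of planted subgroups depends on their tree-consistency: greedy
  growth cannot be expected to reconstruct conjunctions whose members are
  invisible marginally at the root. The interaction example set is
  deliberately hard for main-effects models yet still tree-consistent.
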