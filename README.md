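# adversitree

Weighted classification trees for discovering early-life subgroups at high
risk of adolescent suicidal ideation — and for checking how well such
subgroup rules screen, transport, and compare against a conventional
regression baseline.

## The problem

Population birth-cohort studies measure dozens of dichotomized early-life
risk and protective factors (family adversity, perinatal exposures, parenting
style, socio-economic strain) on thousands of children, then observe adverse
outcomes in adolescence. Individual risk factors are weak and highly
co-occurring; what matters clinically are *constellations* — conjunctions of
factors that define small subgroups with several times the population risk.
`adversitree` implements that subgroup-discovery pipeline for survey-weighted
cohorts with a binary primary outcome (self-reported suicidal thoughts) and
secondary adverse outcomes:

1. **Tree growth.** A CART-style binary classification tree is grown on
   predictors coded *yes* vs *no/missing*, splitting by survey-weighted Gini
   impurity decrease, with one stopping rule: every child node must hold at
   least `n_min` individuals (64 by default — 1% of a cohort of 6,388).
2. **Risk designation.** With base rate `p0` (the weighted outcome
   prevalence), every node is labelled **high** if its weighted prevalence
   `p > 2·p0` (strict), **low** if `p < p0/2` (strict), else **moderate**.
3. **Risk-homogeneity pruning.** Any subtree whose nodes all share one risk
   level is collapsed to its root: splits that no longer differentiate risk
   are discarded while pooled counts and prevalences are conserved.
4. **Profile extraction.** Each high-risk terminal becomes a subgroup
   profile — the conjunction of its root-to-leaf conditions — with its
   training prevalence and size.
5. **Screening diagnostics.** High-risk vs not-high-risk classification is
   evaluated against the primary and six secondary outcomes: sensitivity,
   specificity, PPV, NPV with 95% intervals.
6. **External validation.** Profiles are ported to a second cohort through a
   closest-proxy predictor mapping (noisy and incomplete by nature), with
   explicit policies for conditions that have no substitute.
7. **Baseline.** A stepwise logistic regression (Wald-driven entry/removal)
   provides the main-effects comparator that conjunction-based rules are
   expected to beat on sensitivity when risk is interaction-driven.

Because the motivating survey microdata are restricted-access, the package
ships a **synthetic cohort generator**: correlated binary predictors from a
shared latent adversity factor, gamma survey weights, planted high-risk
subgroups with configurable conjunctions and prevalences, six secondary
outcomes sharing the latent structure, and a linked validation cohort
observed through a noisy predictor mapping. Every stage of the pipeline is
tested end-to-end against this generator's ground truth.

## Worked example

```r
library(adversitree)

spec <- cohort_spec(n_individuals = 6388, n_predictors = 75,
                    base_prevalence = 0.12,
                    planted_subgroups = example_planted_subgroups(75),
                    seed = 2024)
cohort <- generate_cohort(spec)

fit <- discover_subgroups(cohort, config = grow_config(n_min = 64))
fit
#> Subgroup discovery
#>   base rate: 12.3%
#>   terminals: 7 high / 27 moderate / 24 low
#>   flagged high risk: 968 of 6388
#> sensitivity   54.9% (95% CI 51.3, 58.4)
#> specificity   90.6% (95% CI 89.9, 91.4)
#> ppv           45.1% (95% CI 41.9, 48.2)
#> npv           93.5% (95% CI 92.8, 94.1)
```

The cohort's weighted base rate is 12.3%, so nodes above 24.6% prevalence
are designated high risk. Pruning the maximal tree leaves 58 terminals
(7 high / 27 moderate / 24 low); the 968 individuals in high-risk terminals
capture 54.9% of all who report suicidal thoughts while flagging 15% of the
cohort, and 45.1% of the flagged actually report the outcome — 3.7 times the
base rate. The leading profile is a five-condition conjunction containing
the three planted conditions (`x0060`, `x0045`, `x0075` at *yes*) with a
training prevalence of 50.8% (n = 92).

Port the profiles to an independent validation cohort whose predictors are
noisy proxies (here 10% disagreement per variable):

```r
mapping <- predictor_mapping(sprintf("x%04d", 1:75), flip_prob = 0.1)
validation <- make_validation_cohort(spec, mapping)
ported <- port_profiles(fit$profiles, mapping)
cls <- classify_high_risk(ported, validation)
screening_metrics(confusion_table(cls, validation$y_primary,
                                  validation$weight))
```

Sensitivity drops and the profile rule coarsens — the expected behaviour of
a clinical prediction rule transported across imperfectly harmonised
cohorts. The stepwise logistic baseline is one call:

```r
model <- stepwise_select(cohort)
classify_by_probability(model, cohort, threshold = 0.5)
```

A thin command-line wrapper over these functions lives in
`inst/cli/adversitree.R` (subcommands `simulate`, `grow`, `prune`,
`profile`, `validate`, `evaluate`, `baseline`).

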