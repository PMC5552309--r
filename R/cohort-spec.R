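#' Describe one planted high-risk subgroup
#'
#' A planted subgroup is a conjunction of conditions on binary predictors
#' together with the outcome prevalence its members should exhibit. The
#' synthetic generator assigns the primary outcome at this prevalence to every
#' individual matching all conditions (first matching subgroup wins when
#' subgroups overlap).
#'
#' @param conditions Named integer vector: names are predictor labels
#'   (e.g. `"x0075"`), values are the required level, `1` ("yes") or `0`
#'   ("no/missing"). Between 1 and 9 conditions; no predictor may repeat.
#' @param prevalence Outcome prevalence inside the subgroup, in (0, 1).
#' @return An object of class `planted_subgroup`.
#' @seealso [cohort_spec()], [generate_cohort()]
#' @export
planted_subgroup <- function(conditions, prevalence) {
  if (length(conditions) < 1L || length(conditions) > 9L)
    stop("a planted subgroup needs between 1 and 9 conditions")
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("'conditions' must be a named vector of predictor levels")
  if (anyDuplicated(names(conditions)))
    stop("a predictor may appear at most once within a subgroup")
  if (!all(conditions %in% c(0L, 1L)))
    stop("condition levels must be 0 (no/missing) or 1 (yes)")
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1)
    stop("'prevalence' must be a single value in (0, 1)")
  structure(list(conditions = as.integer(conditions),
                 predictors = names(conditions),
                 prevalence = as.numeric(prevalence)),
            class = "planted_subgroup")
}

#' Specify a synthetic early-life cohort
#'
#' Collects every parameter of the synthetic cohort generator: cohort size,
#' number of dichotomized predictors, target weighted prevalence of the
#' primary outcome, six secondary-outcome prevalences, planted high-risk
#' subgroups, per-predictor marginals and missingness, the strength of
#' adversity clustering, and the dispersion of survey weights.
#'
#' Predictors are binary with the "no/missing" convention: level 0 pools true
#' negatives with item non-response. Co-occurrence of adversities is induced
#' by a single latent standard-normal factor per individual shared across
#' predictors (a Gaussian copula with common loading
#' `sqrt(clustering_strength)`), so `clustering_strength = 0` gives
#' independent predictors and values toward 1 give strongly clustered ones.
#' Survey weights are gamma-distributed with mean 1 and coefficient of
#' variation `weight_dispersion` (all 1 when 0), mimicking right-skewed
#' post-stratification weights.
#'
#' Secondary outcomes load on the same latent factor and on planted-subgroup
#' membership (`secondary_loading`, `secondary_member_bump`), so that the
#' subgroups driving the primary outcome also elevate the secondary
#' outcomes -- the multifinality structure the downstream diagnostics probe.
#' Their intercepts are calibrated so each secondary outcome hits its target
#' weighted prevalence.
#'
#' @param n_individuals Number of individuals.
#' @param n_predictors Number of binary predictors (default 75).
#' @param base_prevalence Target overall weighted prevalence of the primary
#'   outcome (default 0.12).
#' @param secondary_prevalences Six target prevalences for the secondary
#'   outcomes, in the order antisocial behaviour, substance misuse, poor
#'   physical health, poor mental health, risky health behaviours, poor
#'   academic performance. Defaults span the 0.114--0.264 range typical of
#'   adolescent adverse outcomes.
#' @param planted_subgroups List of [planted_subgroup()] objects (may be
#'   empty). Condition predictor names must exist given `n_predictors`.
#' @param predictor_marginals Per-predictor probability of level 1 before
#'   missingness, each in (0, 1). Default: evenly spaced 0.05 to 0.5.
#' @param missingness_rates Per-predictor probability that an observed "yes"
#'   is lost to item non-response and folded to 0, each in \[0, 1). Default 0.
#' @param clustering_strength Shared-factor loading squared, in \[0, 1).
#'   Default 0.3.
#' @param weight_dispersion Coefficient of variation of the survey weights,
#'   non-negative. Default 0.5.
#' @param secondary_loading Latent-factor loading of the secondary outcomes
#'   (length 1 or 6; default 0.6).
#' @param secondary_member_bump Log-odds bump for planted-subgroup members on
#'   the secondary outcomes (length 1 or 6; default 1).
#' @param seed Integer seed; identical specs produce identical cohorts.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_individuals = 2000, n_predictors = 10, seed = 1)
#' cohort <- generate_cohort(spec)
#' weighted_prevalence(cohort$y_primary, cohort$weight)
#' @export
cohort_spec <- function(n_individuals,
                        n_predictors = 75L,
                        base_prevalence = 0.12,
                        secondary_prevalences = c(0.17, 0.264, 0.14,
                                                  0.15, 0.114, 0.18),
                        planted_subgroups = list(),
                        predictor_marginals = NULL,
                        missingness_rates = 0,
                        clustering_strength = 0.3,
                        weight_dispersion = 0.5,
                        secondary_loading = 0.6,
                        secondary_member_bump = 1,
                        seed = 1L) {
  n_individuals <- as.integer(n_individuals)
  n_predictors <- as.integer(n_predictors)
  if (n_individuals < 1L) stop("'n_individuals' must be positive")
  if (n_predictors < 1L) stop("'n_predictors' must be positive")
  if (base_prevalence <= 0 || base_prevalence >= 1)
    stop("'base_prevalence' must lie in (0, 1)")
  if (length(secondary_prevalences) != 6L ||
      any(secondary_prevalences <= 0) || any(secondary_prevalences >= 1))
    stop("'secondary_prevalences' must be six proportions in (0, 1)")
  if (is.null(predictor_marginals))
    predictor_marginals <- seq(0.05, 0.5, length.out = n_predictors)
  predictor_marginals <- rep_len(predictor_marginals, n_predictors)
  if (any(predictor_marginals <= 0) || any(predictor_marginals >= 1))
    stop("'predictor_marginals' must lie in (0, 1)")
  missingness_rates <- rep_len(missingness_rates, n_predictors)
  if (any(missingness_rates < 0) || any(missingness_rates >= 1))
    stop("'missingness_rates' must lie in [0, 1)")
  if (clustering_strength < 0 || clustering_strength >= 1)
    stop("'clustering_strength' must lie in [0, 1)")
  if (weight_dispersion < 0) stop("'weight_dispersion' must be non-negative")
  pred_names <- predictor_labels(n_predictors)
  for (sg in planted_subgroups) {
    if (!inherits(sg, "planted_subgroup"))
      stop("'planted_subgroups' must be a list of planted_subgroup objects")
    unknown <- setdiff(sg$predictors, pred_names)
    if (length(unknown))
      stop("subgroup condition references unknown predictor(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(n_individuals = n_individuals,
                 n_predictors = n_predictors,
                 base_prevalence = base_prevalence,
                 secondary_prevalences = as.numeric(secondary_prevalences),
                 planted_subgroups = planted_subgroups,
                 predictor_marginals = as.numeric(predictor_marginals),
                 missingness_rates = as.numeric(missingness_rates),
                 clustering_strength = clustering_strength,
                 weight_dispersion = weight_dispersion,
                 secondary_loading = rep_len(secondary_loading, 6L),
                 secondary_member_bump = rep_len(secondary_member_bump, 6L),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

predictor_labels <- function(p) sprintf("x%04d", seq_len(p))

#' Default planted subgroups mirroring nested early-adversity profiles
#'
#' Four disjoint high-risk subgroups arranged as leaves of a conceptual tree:
#' a sex-like root split, then stressful-event-like and family-structure-like
#' conditions, with within-group outcome prevalences 0.27--0.41 against a 0.12
#' base rate. Predictor indices are taken at fixed fractions of
#' `n_predictors` so the set scales with the spec; the chosen predictors have
#' moderate-to-large marginals, as the influential dichotomized adversities in
#' population cohorts do.
#'
#' @param n_predictors Number of predictors in the target spec (default 75).
#' @return List of [planted_subgroup()] objects.
#' @export
example_planted_subgroups <- function(n_predictors = 75L) {
  p <- as.integer(n_predictors)
  at <- function(f) predictor_labels(p)[max(1L, round(f * p))]
  s <- at(1); a <- at(0.8); b <- at(0.6); cc <- at(0.4)
  d <- at(2 / 3); e <- at(8 / 15); f2 <- at(11 / 15); g <- at(7 / 15)
  cond <- function(levels, preds) stats::setNames(as.integer(levels), preds)
  list(
    planted_subgroup(cond(c(1, 1, 1), c(s, a, b)), 0.41),
    planted_subgroup(cond(c(1, 1, 0, 1), c(s, a, b, cc)), 0.35),
    planted_subgroup(cond(c(1, 0, 1, 1), c(s, a, d, e)), 0.30),
    planted_subgroup(cond(c(0, 1, 1), c(s, f2, g)), 0.27)
  )
}

#' Planted subgroups with opposite-level predictor reuse
#'
#' Three disjoint subgroups that reuse the same few predictors at opposite
#' levels (one group requires a predictor at "yes" where another requires
#' "no"), so their risk is carried by interactions with weak marginal
#' effects. Such cohorts separate interaction-capable classifiers
#' (classification trees) from main-effects logistic regression.
#'
#' @inheritParams example_planted_subgroups
#' @return List of [planted_subgroup()] objects.
#' @export
interaction_planted_subgroups <- function(n_predictors = 20L) {
  p <- as.integer(n_predictors)
  at <- function(f) predictor_labels(p)[max(1L, round(f * p))]
  s <- at(1); a <- at(0.8); b <- at(0.6); cc <- at(0.4)
  cond <- function(levels, preds) stats::setNames(as.integer(levels), preds)
  list(
    planted_subgroup(cond(c(1, 1, 1), c(s, a, b)), 0.38),
    planted_subgroup(cond(c(1, 0, 0, 1), c(s, a, b, cc)), 0.38),
    planted_subgroup(cond(c(0, 1, 0, 0), c(s, a, b, cc)), 0.38)
  )
}
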