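#' End-to-end subgroup discovery on one cohort
#'
#' Convenience wrapper chaining the pipeline: grow the maximal weighted tree
#' under the minimum-node-size rule, designate node risk against the cohort
#' base rate, prune risk-homogeneous subtrees, extract high-risk profiles,
#' classify the cohort and compute screening diagnostics for the primary
#' outcome.
#'
#' @param cohort A `cohort`.
#' @param outcome Outcome column (default `"y_primary"`).
#' @param config A [grow_config()]; default `n_min` 64.
#' @param thresholds Optional [risk_thresholds()]; default 2x / 0.5x around
#'   the cohort base rate.
#' @param ci_method Confidence-interval method for the diagnostics.
#' @return A list of class `subgroup_discovery` with elements `tree` (pruned,
#'   annotated), `profiles`, `classification`, `metrics`
#'   (a `diagnostic_result`), `terminal_counts` and `base_rate`.
#' @examples
#' spec <- cohort_spec(3000, n_predictors = 10,
#'                     planted_subgroups = example_planted_subgroups(10),
#'                     seed = 7)
#' cohort <- generate_cohort(spec)
#' fit <- discover_subgroups(cohort, config = grow_config(n_min = 30))
#' fit$terminal_counts
#' @export
discover_subgroups <- function(cohort, outcome = "y_primary",
                               config = grow_config(),
                               thresholds = NULL,
                               ci_method = "wald") {
  tree <- grow_tree(cohort, outcome, config)
  tree <- annotate_tree(tree, thresholds)
  tree <- prune_tree(tree)
  profiles <- extract_high_risk_profiles(tree)
  classification <- classify_high_risk(profiles, cohort)
  ct <- confusion_table(classification, cohort[[outcome]], cohort$weight)
  metrics <- screening_metrics(ct, ci_method)
  structure(list(tree = tree,
                 profiles = profiles,
                 classification = classification,
                 metrics = metrics,
                 terminal_counts = count_terminals_by_risk(tree),
                 base_rate = tree$base_rate),
            class = "subgroup_discovery")
}

#' @export
print.subgroup_discovery <- function(x, ...) {
  cat("Subgroup discovery\n")
  cat(sprintf("  base rate: %.1f%%\n", 100 * x$base_rate))
  cat(sprintf("  terminals: %d high / %d moderate / %d low\n",
              x$terminal_counts[["high"]], x$terminal_counts[["moderate"]],
              x$terminal_counts[["low"]]))
  cat(sprintf("  flagged high risk: %d of %d\n",
              sum(x$classification$flag), nrow(x$classification)))
  print(x$metrics)
  invisible(x)
}
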