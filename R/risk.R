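#' Risk designation thresholds
#'
#' Nodes are labelled relative to the base rate of the analysis cohort:
#' prevalence strictly greater than `high_multiplier` times the base rate is
#' high risk, strictly less than `low_multiplier` times the base rate is low
#' risk, and anything between (boundaries included) is moderate.
#'
#' @param base_rate Overall weighted outcome prevalence, in (0, 1).
#' @param high_multiplier High-risk cut-off multiplier (default 2).
#' @param low_multiplier Low-risk cut-off multiplier (default 0.5).
#' @return An object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(base_rate, high_multiplier = 2,
                            low_multiplier = 0.5) {
  if (base_rate <= 0 || base_rate >= 1)
    stop("'base_rate' must lie in (0, 1)")
  if (low_multiplier >= high_multiplier)
    stop("'low_multiplier' must be below 'high_multiplier'")
  if (high_multiplier <= 0) stop("multipliers must be positive")
  if (base_rate * high_multiplier > 1)
    stop("high-risk cut-off exceeds 1; lower 'high_multiplier'")
  structure(list(base_rate = base_rate,
                 high_multiplier = high_multiplier,
                 low_multiplier = low_multiplier),
            class = "risk_thresholds")
}

#' Designate risk level from a node prevalence
#'
#' @param prevalence Node prevalence(s) in \[0, 1\]; vectorized.
#' @param thresholds A [risk_thresholds()].
#' @return Character vector over `{"high", "moderate", "low"}`.
#' @examples
#' th <- risk_thresholds(0.12)
#' designate_risk(c(0.406, 0.24, 0.059), th)  # high, moderate, low
#' @export
designate_risk <- function(prevalence, thresholds) {
  stopifnot(inherits(thresholds, "risk_thresholds"))
  if (any(prevalence < 0 | prevalence > 1))
    stop("'prevalence' must lie in [0, 1]")
  hi <- thresholds$high_multiplier * thresholds$base_rate
  lo <- thresholds$low_multiplier * thresholds$base_rate
  ifelse(prevalence > hi, "high", ifelse(prevalence < lo, "low", "moderate"))
}

#' Annotate every tree node with its risk level
#'
#' Applies [designate_risk()] to the weighted prevalence of every node,
#' terminal and internal, and stores the thresholds on the tree. Annotation
#' is idempotent and changes nothing else.
#'
#' @param tree A `risk_tree`.
#' @param thresholds A [risk_thresholds()]; by default built from the tree's
#'   own base rate with the 2x / 0.5x multipliers.
#' @return The annotated `risk_tree`.
#' @export
annotate_tree <- function(tree, thresholds = NULL) {
  stopifnot(inherits(tree, "risk_tree"))
  if (is.null(thresholds)) thresholds <- risk_thresholds(tree$base_rate)
  for (id in seq_along(tree$nodes)) {
    if (is.null(tree$nodes[[id]])) next
    tree$nodes[[id]]$risk_level <-
      designate_risk(tree$nodes[[id]]$weighted_prevalence, thresholds)
  }
  tree$thresholds <- thresholds
  tree
}

#' Prune risk-homogeneous subtrees
#'
#' Bottom-up pruning of an annotated tree: any internal node whose entire
#' subtree -- the node itself and all descendants, internal nodes included --
#' carries one risk level is collapsed into a terminal with that level. The
#' collapsed node keeps its pooled unweighted count, weighted total and
#' weighted prevalence (which, by construction, equal the totals of the
#' removed terminals), so pruning conserves every individual's contribution;
#' each pruned terminal is a union of original terminals. The operation is
#' idempotent and leaves no internal node with a risk-homogeneous subtree.
#'
#' @param tree An annotated `risk_tree` (see [annotate_tree()]).
#' @return The pruned, annotated `risk_tree`.
#' @export
prune_tree <- function(tree) {
  stopifnot(inherits(tree, "risk_tree"))
  nodes <- tree$nodes
  check_annotated <- function(nd) {
    if (is.null(nd$risk_level))
      stop("node ", nd$node_id, " is not annotated; run annotate_tree() first")
  }

  # level shared by the whole subtree, or NA when heterogeneous
  subtree_level <- function(id) {
    nd <- nodes[[id]]
    check_annotated(nd)
    if (is_terminal(nd)) return(nd$risk_level)
    lv_yes <- subtree_level(nd$yes_child)
    lv_no <- subtree_level(nd$no_child)
    if (!is.na(lv_yes) && identical(lv_yes, lv_no) &&
        identical(lv_yes, nd$risk_level)) lv_yes else NA_character_
  }

  keep <- logical(length(nodes))
  collapse <- function(id) {
    keep[id] <<- TRUE
    nd <- nodes[[id]]
    if (is_terminal(nd)) return(invisible())
    if (!is.na(subtree_level(id))) {
      nodes[[id]]$split_predictor <<- NA_character_
      nodes[[id]]$yes_child <<- NA_integer_
      nodes[[id]]$no_child <<- NA_integer_
    } else {
      collapse(nd$yes_child)
      collapse(nd$no_child)
    }
  }
  collapse(tree$root_id)
  for (id in seq_along(nodes)) if (!keep[id]) nodes[id] <- list(NULL)
  tree$nodes <- nodes
  tree
}

#' Count terminal nodes per risk level
#'
#' @param tree An annotated `risk_tree`.
#' @return Named integer vector with elements `high`, `moderate`, `low`,
#'   summing to the number of terminals.
#' @export
count_terminals_by_risk <- function(tree) {
  terms <- terminal_nodes(tree)
  lv <- vapply(terms, function(nd) {
    if (is.null(nd$risk_level))
      stop("tree is not annotated; run annotate_tree() first")
    nd$risk_level
  }, character(1))
  c(high = sum(lv == "high"),
    moderate = sum(lv == "moderate"),
    low = sum(lv == "low"))
}
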