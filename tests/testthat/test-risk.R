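# annotated trees grown on random cohorts, with thresholds around the
# cohort base rate
random_annotated_tree <- function(seed, n = 250, p = 5, n_min = 12) {
  coh <- random_cohort(n, p, seed)
  annotate_tree(grow_tree(coh, config = grow_config(n_min = n_min)))
}

test_that("risk designation uses strict 2x / half-base cut-offs", {
  th <- risk_thresholds(0.12)
  expect_identical(designate_risk(0.406, th), "high")
  expect_identical(designate_risk(0.24, th), "moderate")  # boundary: strict
  expect_identical(designate_risk(0.06, th), "moderate")  # boundary: strict
  expect_identical(designate_risk(0.059, th), "low")
  expect_identical(designate_risk(0.2401, th), "high")
  # monotone in prevalence
  lv <- designate_risk(seq(0, 1, by = 0.001), th)
  rank <- c(low = 1, moderate = 2, high = 3)[lv]
  expect_true(all(diff(rank) >= 0))
})

test_that("threshold invariants are enforced", {
  expect_error(risk_thresholds(0.6, high_multiplier = 2), "exceeds 1")
  expect_error(risk_thresholds(0.12, high_multiplier = 1, low_multiplier = 2),
               "below")
})

test_that("annotation covers every node and is idempotent", {
  tree <- random_annotated_tree(1)
  nodes <- Filter(Negate(is.null), tree$nodes)
  expect_true(all(vapply(nodes, function(nd)
    nd$risk_level %in% c("high", "moderate", "low"), logical(1))))
  for (nd in nodes)
    expect_identical(nd$risk_level,
                     designate_risk(nd$weighted_prevalence, tree$thresholds))
  expect_identical(annotate_tree(tree, tree$thresholds), tree)
  # a root-only tree sits exactly at its own base rate: moderate
  coh <- random_cohort(30, 2, seed = 3)
  single <- annotate_tree(grow_tree(coh, config = grow_config(n_min = 40)))
  expect_identical(single$nodes[[single$root_id]]$risk_level, "moderate")
})

test_that("pruning collapses a fully low subtree to one low terminal", {
  leaf <- function(lv) list(level = lv, n = 10L, w = 10,
                            prev = c(high = 0.5, moderate = 0.12,
                                     low = 0.02)[[lv]])
  shape <- list(level = "low",
                yes = list(level = "low", yes = leaf("low"), no = leaf("low")),
                no = leaf("low"))
  tree <- tree_from_shape(shape)
  tree$thresholds <- risk_thresholds(0.12)
  pruned <- prune_tree(tree)
  terms <- terminal_nodes(pruned)
  expect_length(terms, 1)
  expect_identical(terms[[1]]$risk_level, "low")
  expect_equal(terms[[1]]$n_unweighted, 30L)
})

test_that("heterogeneous children block pruning", {
  leaf <- function(lv) list(level = lv, n = 10L, w = 10,
                            prev = c(high = 0.5, moderate = 0.12,
                                     low = 0.02)[[lv]])
  shape <- list(level = "moderate", yes = leaf("high"), no = leaf("low"))
  tree <- tree_from_shape(shape)
  pruned <- prune_tree(tree)
  expect_length(terminal_nodes(pruned), 2)
  expect_false(is.na(pruned$nodes[[pruned$root_id]]$split_predictor))
})

test_that("an internal node's own level participates in homogeneity", {
  leaf <- function(lv) list(level = lv, n = 10L, w = 10,
                            prev = c(high = 0.5, moderate = 0.12,
                                     low = 0.02)[[lv]])
  # both leaves low but the parent itself moderate: must NOT collapse
  shape <- list(level = "moderate",
                yes = list(level = "moderate", yes = leaf("low"),
                           no = leaf("low")),
                no = leaf("moderate"))
  pruned <- prune_tree(tree_from_shape(shape))
  inner <- pruned$nodes[[pruned$nodes[[pruned$root_id]]$yes_child]]
  expect_false(is.na(inner$split_predictor))
})

test_that("pruning is idempotent and conserves pooled totals on grown trees", {
  for (seed in 1:20) {
    tree <- random_annotated_tree(seed)
    pruned <- prune_tree(tree)
    expect_identical(prune_tree(pruned), pruned)
    # conservation of individuals and weight across collapse
    tot_n <- function(t) sum(vapply(terminal_nodes(t), `[[`, integer(1),
                                    "n_unweighted"))
    tot_w <- function(t) sum(vapply(terminal_nodes(t), `[[`, numeric(1),
                                    "weighted_n"))
    tot_wy <- function(t) sum(vapply(terminal_nodes(t), function(nd)
      nd$weighted_n * nd$weighted_prevalence, numeric(1)))
    expect_equal(tot_n(pruned), tot_n(tree))
    expect_equal(tot_w(pruned), tot_w(tree), tolerance = 1e-9)
    expect_equal(tot_wy(pruned), tot_wy(tree), tolerance = 1e-9)
    expect_lte(length(terminal_nodes(pruned)), length(terminal_nodes(tree)))
    # every pruned terminal is a union of original terminals: its node id
    # existed in the original tree with identical counts
    for (nd in terminal_nodes(pruned)) {
      orig <- tree$nodes[[nd$node_id]]
      expect_equal(orig$n_unweighted, nd$n_unweighted)
      expect_equal(orig$weighted_prevalence, nd$weighted_prevalence)
    }
    # no surviving internal node has a risk-homogeneous subtree
    expect_equal(length(terminal_nodes(pruned)), ref_min_terminals(pruned))
  }
})

test_that("pruned terminal count is minimal: exhaustive check on small trees", {
  for (k in 0:3) {               # up to 3 internal nodes = 7 nodes
    for (shape in all_shapes(k)) {
      n_nodes <- count_shape_nodes(shape)
      grids <- expand.grid(rep(list(c("high", "moderate", "low")), n_nodes),
                           stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grids))) {
        lv <- as.character(grids[r, ])
        tree <- tree_from_shape(shape_with_levels(shape, lv))
        pruned <- prune_tree(tree)
        expect_identical(length(terminal_nodes(pruned)),
                         ref_min_terminals(tree))
      }
    }
  }
})

test_that("unannotated trees are rejected by prune and counts", {
  coh <- random_cohort(100, 3, seed = 2)
  tree <- grow_tree(coh, config = grow_config(n_min = 10))
  expect_error(prune_tree(tree), "not annotated")
  expect_error(count_terminals_by_risk(tree), "not annotated")
})

test_that("terminal counts per level match a direct traversal", {
  # the nine published-style subgroup prevalences under base 0.12: all high
  th <- risk_thresholds(0.12)
  prevs <- c(0.406, 0.394, 0.309, 0.307, 0.304, 0.300, 0.277, 0.266, 0.253)
  expect_true(all(designate_risk(prevs, th) == "high"))
  tree <- prune_tree(random_annotated_tree(33))
  counts <- count_terminals_by_risk(tree)
  lv <- vapply(terminal_nodes(tree), `[[`, character(1), "risk_level")
  expect_equal(counts[["high"]], sum(lv == "high"))
  expect_equal(counts[["moderate"]], sum(lv == "moderate"))
  expect_equal(counts[["low"]], sum(lv == "low"))
  expect_equal(sum(counts), length(lv))
})
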