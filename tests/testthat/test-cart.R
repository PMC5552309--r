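test_that("weighted prevalence matches closed forms and the summation oracle", {
  expect_equal(weighted_prevalence(c(1, 0, 0, 1), rep(1, 4)), 0.5)
  # two gender strata, weighted shares 49.5%/50.5%, prevalences 15.6%/8.5%:
  # expand each stratum into outcome-1 and outcome-0 mass
  y <- c(1, 0, 1, 0)
  w <- c(0.495 * 0.156, 0.495 * 0.844, 0.505 * 0.085, 0.505 * 0.915)
  expect_equal(round(weighted_prevalence(y, w), 4), 0.1201)
  set.seed(42)
  yr <- rbinom(100, 1, 0.3); wr <- runif(100)
  expect_equal(weighted_prevalence(yr, wr), ref_weighted_prevalence(yr, wr),
               tolerance = 1e-12)
  expect_error(weighted_prevalence(c(0, 1), c(0, 0)), "total weight")
  expect_error(weighted_prevalence(c(0, 1), c(1, 1, 1)), "equal length")
})

test_that("evaluate_split matches the brute-force Gini oracle", {
  coh <- random_cohort(8, 3, seed = 5, unit_weights = TRUE)
  for (pred in predictor_columns(coh)) {
    cand <- evaluate_split(coh, pred, grow_config(n_min = 1))
    expect_equal(cand$impurity_decrease,
                 ref_split_decrease(coh, pred, 1:8), tolerance = 1e-12)
    expect_equal(cand$n_yes + cand$n_no, 8)
  }
})

test_that("a pure node admits no impurity decrease", {
  coh <- random_cohort(20, 3, seed = 1)
  coh$y_primary <- 1L
  for (pred in predictor_columns(coh))
    expect_equal(evaluate_split(coh, pred)$impurity_decrease, 0)
})

test_that("a perfectly separating predictor recovers the parent Gini", {
  coh <- random_cohort(40, 2, seed = 2, unit_weights = TRUE)
  coh$x0001 <- coh$y_primary
  cand <- evaluate_split(coh, "x0001", grow_config(n_min = 1))
  p <- mean(coh$y_primary)
  expect_equal(cand$impurity_decrease, 2 * p * (1 - p), tolerance = 1e-12)
})

test_that("best_split enforces the child-size rule and deterministic ties", {
  # pigeonhole: n = 100 cannot give two children of 64
  coh <- random_cohort(100, 4, seed = 3)
  expect_null(best_split(coh, grow_config(n_min = 64)))
  # duplicated optimal predictors: lowest column position wins
  coh2 <- random_cohort(60, 1, seed = 4)
  coh2$x0002 <- coh2$x0001
  class(coh2) <- c("cohort", "data.frame")
  best <- best_split(coh2, grow_config(n_min = 5))
  expect_identical(best$predictor, "x0001")
  # agreement with exhaustive enumeration
  for (seed in 1:5) {
    coh3 <- random_cohort(200, 6, seed = seed)
    got <- best_split(coh3, grow_config(n_min = 10))
    want <- ref_best_split(coh3, 1:200, n_min = 10)
    expect_identical(got$predictor, want$predictor)
    expect_equal(got$impurity_decrease, want$decrease, tolerance = 1e-12)
  }
})

test_that("growth stops below the minimum node size", {
  coh <- random_cohort(10, 3, seed = 6)
  tree <- grow_tree(coh, config = grow_config(n_min = 64))
  expect_length(live_nodes <- Filter(Negate(is.null), tree$nodes), 1)
  expect_true(is.na(tree$nodes[[tree$root_id]]$split_predictor))
})

test_that("a single determining predictor yields a depth-1 pure tree", {
  set.seed(7)
  coh <- random_cohort(50, 3, seed = 7)
  coh$y_primary <- coh$x0001
  tree <- grow_tree(coh, config = grow_config(n_min = 1))
  root <- tree$nodes[[tree$root_id]]
  expect_identical(root$split_predictor, "x0001")
  yes <- tree$nodes[[root$yes_child]]; no <- tree$nodes[[root$no_child]]
  expect_true(is.na(yes$split_predictor) && is.na(no$split_predictor))
  expect_equal(yes$weighted_prevalence, 1)
  expect_equal(no$weighted_prevalence, 0)
})

test_that("grown trees match the independent recursive partitioner", {
  for (seed in 1:10) {
    coh <- random_cohort(200, 6, seed = 100 + seed)
    tree <- grow_tree(coh, config = grow_config(n_min = 10))
    ref <- ref_grow(coh, 1:200, n_min = 10)
    expect_true(trees_agree(tree, tree$root_id, ref))
  }
})

test_that("unweighted splitting is honoured when requested", {
  coh <- random_cohort(300, 5, seed = 31)
  tree <- grow_tree(coh, config = grow_config(n_min = 20,
                                              use_weights_in_splitting = FALSE))
  ref <- ref_grow(coh, 1:300, n_min = 20, use_weights = FALSE)
  expect_true(trees_agree(tree, tree$root_id, ref))
})

test_that("terminals partition the cohort and conserve totals", {
  coh <- random_cohort(300, 6, seed = 8)
  tree <- grow_tree(coh, config = grow_config(n_min = 15))
  terms <- terminal_nodes(tree)
  expect_equal(sum(vapply(terms, `[[`, integer(1), "n_unweighted")), 300)
  expect_equal(sum(vapply(terms, `[[`, numeric(1), "weighted_n")),
               sum(coh$weight), tolerance = 1e-9)
  # parent prevalence is the weighted mean of its children's
  for (nd in Filter(function(n) !is.na(n$split_predictor),
                    Filter(Negate(is.null), tree$nodes))) {
    yes <- tree$nodes[[nd$yes_child]]; no <- tree$nodes[[nd$no_child]]
    expect_equal(nd$weighted_prevalence,
                 (yes$weighted_prevalence * yes$weighted_n +
                    no$weighted_prevalence * no$weighted_n) / nd$weighted_n,
                 tolerance = 1e-9)
    expect_gte(yes$n_unweighted, 15)
    expect_gte(no$n_unweighted, 15)
    expect_equal(nrow(yes$path_conditions), yes$depth)
  }
})

test_that("descend reproduces the training partition exactly", {
  coh <- random_cohort(250, 5, seed = 9)
  tree <- grow_tree(coh, config = grow_config(n_min = 12))
  leaf_ids <- vapply(seq_len(nrow(coh)), function(i)
    descend(tree, coh[i, predictor_columns(coh)])$node_id, integer(1))
  counts <- table(leaf_ids)
  for (nd in terminal_nodes(tree))
    expect_equal(unname(counts[as.character(nd$node_id)]),
                 nd$n_unweighted, ignore_attr = TRUE)
  # root-only tree sends everyone to the root
  tiny <- grow_tree(coh, config = grow_config(n_min = 300))
  expect_equal(descend(tiny, coh[1, ])$node_id, tiny$root_id)
  # missing predictor is reported by name
  deep <- coh[1, predictor_columns(coh)]
  deep$x0001 <- NA
  expect_error(descend(tree, deep), "x0001")
})

test_that("growth is deterministic including node ids", {
  coh <- random_cohort(300, 6, seed = 10)
  t1 <- grow_tree(coh, config = grow_config(n_min = 20))
  t2 <- grow_tree(coh, config = grow_config(n_min = 20))
  expect_identical(t1, t2)
})

test_that("max_depth caps the tree", {
  coh <- random_cohort(400, 6, seed = 12)
  tree <- grow_tree(coh, config = grow_config(n_min = 5, max_depth = 2))
  depths <- vapply(Filter(Negate(is.null), tree$nodes), `[[`,
                   integer(1), "depth")
  expect_lte(max(depths), 2)
})

test_that("tree JSON serialization round-trips", {
  coh <- random_cohort(200, 5, seed = 14)
  tree <- annotate_tree(grow_tree(coh, config = grow_config(n_min = 20)))
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tree, path)
  back <- read_tree_json(path)
  expect_equal(back$base_rate, tree$base_rate, tolerance = 1e-12)
  expect_identical(length(Filter(Negate(is.null), back$nodes)),
                   length(Filter(Negate(is.null), tree$nodes)))
  for (nd in Filter(Negate(is.null), tree$nodes)) {
    bn <- back$nodes[[nd$node_id]]
    expect_identical(bn$split_predictor, nd$split_predictor)
    expect_equal(bn$weighted_prevalence, nd$weighted_prevalence,
                 tolerance = 1e-12)
    expect_identical(bn$risk_level, nd$risk_level)
    expect_equal(bn$path_conditions$predictor, nd$path_conditions$predictor)
  }
})
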