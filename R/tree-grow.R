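#' Tree-growing configuration
#'
#' @param n_min Minimum number of (unweighted) individuals required in each
#'   child node for a split to be admissible. The head-count rule: survey
#'   weights never enter it. Default 64, i.e. 1% of a cohort of 6,388.
#' @param min_impurity_decrease Minimum Gini impurity decrease a split must
#'   exceed (strictly) to be admissible. Default 0: the tree is grown
#'   maximally under the node-size rule alone.
#' @param max_depth Optional depth cap; `Inf` (default) grows unbounded.
#' @param use_weights_in_splitting Use survey weights inside the impurity
#'   computation (default `TRUE`). Node prevalences are always weighted.
#' @return An object of class `grow_config`.
#' @export
grow_config <- function(n_min = 64L, min_impurity_decrease = 0,
                        max_depth = Inf, use_weights_in_splitting = TRUE) {
  n_min <- as.integer(n_min)
  if (n_min < 1L) stop("'n_min' must be at least 1")
  if (min_impurity_decrease < 0)
    stop("'min_impurity_decrease' must be non-negative")
  if (!identical(max_depth, Inf) && max_depth < 1)
    stop("'max_depth' must be positive")
  structure(list(n_min = n_min,
                 min_impurity_decrease = min_impurity_decrease,
                 max_depth = max_depth,
                 use_weights_in_splitting = isTRUE(use_weights_in_splitting)),
            class = "grow_config")
}

#' Survey-weighted prevalence of a binary outcome
#'
#' Computes the Horvitz-Thompson-style weighted proportion
#' `sum(w * y) / sum(w)`.
#'
#' @param outcomes Binary (0/1) vector.
#' @param weights Non-negative weights of the same length.
#' @return Weighted prevalence in \[0, 1\].
#' @examples
#' weighted_prevalence(c(1, 0, 0, 1), rep(1, 4))  # 0.5
#' @export
weighted_prevalence <- function(outcomes, weights) {
  if (length(outcomes) != length(weights))
    stop("'outcomes' and 'weights' must have equal length")
  if (any(weights < 0)) stop("weights must be non-negative")
  tot <- sum(weights)
  if (tot <= 0) stop("total weight must be positive")
  sum(weights * outcomes) / tot
}

gini_impurity <- function(p) 2 * p * (1 - p)

# Split statistics for every predictor of `X` restricted to `rows`:
# impurity decrease plus unweighted/weighted child sizes, vectorized over
# columns. The yes child is predictor == 1.
split_statistics <- function(X, y, w, rows, config) {
  Xs <- X[rows, , drop = FALSE]
  yv <- y[rows]
  wv <- if (config$use_weights_in_splitting) w[rows] else rep(1, length(rows))
  n_yes <- colSums(Xs)
  n_no <- length(rows) - n_yes
  w_yes <- as.numeric(crossprod(Xs, wv))
  wy_yes <- as.numeric(crossprod(Xs, wv * yv))
  w_tot <- sum(wv)
  wy_tot <- sum(wv * yv)
  w_no <- w_tot - w_yes
  wy_no <- wy_tot - wy_yes
  p_parent <- wy_tot / w_tot
  p_yes <- ifelse(w_yes > 0, wy_yes / w_yes, 0)
  p_no <- ifelse(w_no > 0, wy_no / w_no, 0)
  decrease <- gini_impurity(p_parent) -
    (w_yes / w_tot) * gini_impurity(p_yes) -
    (w_no / w_tot) * gini_impurity(p_no)
  decrease[n_yes == 0 | n_no == 0] <- 0
  decrease <- pmax(decrease, 0)  # guard tiny negative float residue
  list(decrease = decrease, n_yes = n_yes, n_no = n_no,
       w_yes = w_yes, w_no = w_no)
}

#' Evaluate one candidate split
#'
#' Partitions the given rows by `predictor == 1` versus `== 0` and returns
#' the Gini impurity decrease together with child sizes. Degenerate splits
#' (an empty side) have decrease 0.
#'
#' @param cohort A `cohort`.
#' @param predictor Predictor column name.
#' @param config A [grow_config()].
#' @param outcome Outcome column (default `"y_primary"`).
#' @param rows Integer row indices of the node (default: all rows).
#' @return A list of class `split_candidate` with elements `predictor`,
#'   `impurity_decrease`, `n_yes`, `n_no`, `w_yes`, `w_no`.
#' @export
evaluate_split <- function(cohort, predictor, config = grow_config(),
                           outcome = "y_primary",
                           rows = seq_len(nrow(cohort))) {
  X <- as.matrix(cohort[, predictor, drop = FALSE])
  st <- split_statistics(X, cohort[[outcome]], cohort$weight, rows, config)
  structure(list(predictor = predictor,
                 impurity_decrease = st$decrease[1],
                 n_yes = st$n_yes[[1]], n_no = st$n_no[[1]],
                 w_yes = st$w_yes[1], w_no = st$w_no[1]),
            class = "split_candidate")
}

#' Best admissible split of a node
#'
#' Scans every predictor and returns the candidate with maximal impurity
#' decrease among those whose children both hold at least `n_min`
#' (unweighted) individuals and whose decrease strictly exceeds
#' `min_impurity_decrease`. Ties are broken by the lowest predictor column
#' position, so growth is deterministic.
#'
#' @inheritParams evaluate_split
#' @return A `split_candidate`, or `NULL` when no admissible split exists.
#' @export
best_split <- function(cohort, config = grow_config(),
                       outcome = "y_primary",
                       rows = seq_len(nrow(cohort))) {
  preds <- predictor_columns(cohort)
  X <- as.matrix(cohort[, preds, drop = FALSE])
  j <- best_split_index(X, cohort[[outcome]], cohort$weight, rows, config)
  if (is.null(j)) return(NULL)
  evaluate_split(cohort, preds[j], config, outcome, rows)
}

best_split_index <- function(X, y, w, rows, config) {
  st <- split_statistics(X, y, w, rows, config)
  ok <- st$n_yes >= config$n_min & st$n_no >= config$n_min &
    st$decrease > config$min_impurity_decrease
  if (!any(ok)) return(NULL)
  dec <- ifelse(ok, st$decrease, -Inf)
  # mathematically tied candidates (e.g. complementary partitions) can
  # differ by float rounding; treat near-ties as ties so the lowest column
  # position wins deterministically
  which(dec >= max(dec) - 1e-10)[1]
}

#' Grow the maximal weighted classification tree
#'
#' Recursively partitions the cohort by binary predictor splits that maximize
#' the survey-weighted Gini impurity decrease, splitting depth-first until no
#' node admits a split with both children at or above `n_min` unweighted
#' individuals. Every node records its unweighted count, weighted total,
#' weighted outcome prevalence, depth and the ordered path conditions from
#' the root. Node ids are assigned in preorder (root = 1, yes subtree before
#' no subtree), so identical input yields an identical tree.
#'
#' @param cohort A `cohort`.
#' @param outcome Outcome column name (default `"y_primary"`).
#' @param config A [grow_config()].
#' @return An object of class `risk_tree`: a list with `nodes` (list indexed
#'   by node id), `root_id`, `base_rate` (weighted prevalence at the root),
#'   `outcome` and `config`.
#' @export
grow_tree <- function(cohort, outcome = "y_primary", config = grow_config()) {
  if (nrow(cohort) == 0L) stop("cannot grow a tree on an empty cohort")
  if (!outcome %in% names(cohort)) stop("no outcome column '", outcome, "'")
  y <- cohort[[outcome]]
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary 0/1")
  w <- cohort$weight
  preds <- predictor_columns(cohort)
  X <- as.matrix(cohort[, preds, drop = FALSE])
  config <- if (inherits(config, "grow_config")) config else
    do.call(grow_config, config)

  nodes <- list()
  next_id <- 1L

  build <- function(rows, depth, path) {
    id <- next_id; next_id <<- next_id + 1L
    node <- list(node_id = id,
                 split_predictor = NA_character_,
                 yes_child = NA_integer_, no_child = NA_integer_,
                 n_unweighted = length(rows),
                 weighted_n = sum(w[rows]),
                 weighted_prevalence = weighted_prevalence(y[rows], w[rows]),
                 depth = depth,
                 path_conditions = path)
    nodes[[id]] <<- node
    if (depth < config$max_depth) {
      j <- best_split_index(X, y, w, rows, config)
      if (!is.null(j)) {
        pred <- preds[j]
        yes_rows <- rows[X[rows, j] == 1L]
        no_rows <- rows[X[rows, j] == 0L]
        yes_id <- build(yes_rows, depth + 1L,
                        rbind(path, data.frame(predictor = pred,
                                               level = "yes")))
        no_id <- build(no_rows, depth + 1L,
                       rbind(path, data.frame(predictor = pred,
                                              level = "no")))
        nodes[[id]]$split_predictor <<- pred
        nodes[[id]]$yes_child <<- yes_id
        nodes[[id]]$no_child <<- no_id
      }
    }
    id
  }

  empty_path <- data.frame(predictor = character(0), level = character(0))
  root_id <- build(seq_len(nrow(cohort)), 0L, empty_path)
  structure(list(nodes = nodes, root_id = root_id,
                 base_rate = nodes[[root_id]]$weighted_prevalence,
                 outcome = outcome, config = config),
            class = "risk_tree")
}

is_terminal <- function(node) is.na(node$split_predictor)

#' Terminal nodes of a tree
#'
#' @param tree A `risk_tree`.
#' @return List of terminal node records.
#' @export
terminal_nodes <- function(tree) {
  Filter(is_terminal, tree$nodes[!vapply(tree$nodes, is.null, logical(1))])
}

live_nodes <- function(tree) {
  tree$nodes[!vapply(tree$nodes, is.null, logical(1))]
}

#' Send one individual down the tree
#'
#' Follows yes/no children according to the individual's predictor values
#' until a terminal node is reached.
#'
#' @param tree A `risk_tree`.
#' @param row A named vector, list or one-row data frame providing every
#'   predictor the tree splits on (values 0/1).
#' @return The terminal node record (a list).
#' @export
descend <- function(tree, row) {
  row <- as.list(row)
  node <- tree$nodes[[tree$root_id]]
  while (!is_terminal(node)) {
    pred <- node$split_predictor
    val <- row[[pred]]
    if (is.null(val) || is.na(val))
      stop("row lacks predictor '", pred, "' required by the tree")
    node <- tree$nodes[[if (val == 1) node$yes_child else node$no_child]]
  }
  node
}

#' @export
print.risk_tree <- function(x, ...) {
  nodes <- live_nodes(x)
  terms <- Filter(is_terminal, nodes)
  cat("Weighted classification tree\n")
  cat(sprintf("  outcome: %s   base rate: %.4f\n", x$outcome, x$base_rate))
  cat(sprintf("  nodes: %d   terminals: %d   n: %d\n",
              length(nodes), length(terms),
              x$nodes[[x$root_id]]$n_unweighted))
  if (!is.null(x$thresholds)) {
    ct <- count_terminals_by_risk(x)
    cat(sprintf("  risk terminals: %d high / %d moderate / %d low\n",
                ct[["high"]], ct[["moderate"]], ct[["low"]]))
  }
  invisible(x)
}
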