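# Independent brute-force oracles, deliberately written as plain loops over
# data frames so they share no code path with the package internals.

ref_weighted_prevalence <- function(y, w) {
  num <- 0; den <- 0
  for (i in seq_along(y)) {
    num <- num + w[i] * y[i]
    den <- den + w[i]
  }
  num / den
}

ref_gini <- function(y, w) {
  p <- ref_weighted_prevalence(y, w)
  2 * p * (1 - p)
}

# Gini decrease for one predictor on a subset of rows, by explicit partition.
ref_split_decrease <- function(df, pred, rows, use_weights = TRUE) {
  w <- if (use_weights) df$weight else rep(1, nrow(df))
  yes <- rows[df[[pred]][rows] == 1]
  no <- rows[df[[pred]][rows] == 0]
  if (length(yes) == 0 || length(no) == 0) return(0)
  g_parent <- ref_gini(df$y_primary[rows], w[rows])
  w_yes <- sum(w[yes]); w_no <- sum(w[no]); w_tot <- w_yes + w_no
  g_parent -
    (w_yes / w_tot) * ref_gini(df$y_primary[yes], w[yes]) -
    (w_no / w_tot) * ref_gini(df$y_primary[no], w[no])
}

# Best admissible split: loop over predictors in column order, keep the
# strictly better candidate so ties resolve to the lowest index.
ref_best_split <- function(df, rows, n_min, min_decrease = 0,
                           use_weights = TRUE) {
  best <- NULL
  for (pred in grep("^x[0-9]+$", names(df), value = TRUE)) {
    n_yes <- sum(df[[pred]][rows] == 1)
    n_no <- length(rows) - n_yes
    if (n_yes < n_min || n_no < n_min) next
    dec <- ref_split_decrease(df, pred, rows, use_weights)
    if (dec <= min_decrease) next
    if (is.null(best) || dec > best$decrease + 1e-10)
      best <- list(predictor = pred, decrease = dec)
  }
  best
}

# Recursive reference partitioner; returns a nested list.
ref_grow <- function(df, rows, n_min, min_decrease = 0, use_weights = TRUE) {
  node <- list(n = length(rows),
               prevalence = ref_weighted_prevalence(df$y_primary[rows],
                                                    df$weight[rows]))
  sp <- ref_best_split(df, rows, n_min, min_decrease, use_weights)
  if (!is.null(sp)) {
    node$predictor <- sp$predictor
    node$yes <- ref_grow(df, rows[df[[sp$predictor]][rows] == 1],
                         n_min, min_decrease, use_weights)
    node$no <- ref_grow(df, rows[df[[sp$predictor]][rows] == 0],
                        n_min, min_decrease, use_weights)
  }
  node
}

# Walk a grown risk_tree and the reference tree together; TRUE iff they
# agree node-for-node on split predictor, size and prevalence.
trees_agree <- function(tree, id, ref) {
  nd <- tree$nodes[[id]]
  if (nd$n_unweighted != ref$n) return(FALSE)
  if (abs(nd$weighted_prevalence - ref$prevalence) > 1e-9) return(FALSE)
  ref_terminal <- is.null(ref$predictor)
  if (is.na(nd$split_predictor) != ref_terminal) return(FALSE)
  if (ref_terminal) return(TRUE)
  if (nd$split_predictor != ref$predictor) return(FALSE)
  trees_agree(tree, nd$yes_child, ref$yes) &&
    trees_agree(tree, nd$no_child, ref$no)
}

# Random test cohort: correlated-ish binary predictors, outcome linked to the
# first predictors so trees have structure to find.
random_cohort <- function(n, p, seed, unit_weights = FALSE) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, runif(p, 0.2, 0.8)[rep(seq_len(p),
                                                      each = n)]), n, p)
  colnames(X) <- sprintf("x%04d", seq_len(p))
  eta <- -1.5 + 1.2 * X[, 1] - 0.8 * X[, min(2, p)] +
    0.6 * X[, min(3, p)] * X[, 1]
  y <- rbinom(n, 1, plogis(eta))
  w <- if (unit_weights) rep(1, n) else runif(n, 0.2, 2)
  df <- data.frame(id = sprintf("id%05d", seq_len(n)), weight = w,
                   y_primary = y)
  df <- cbind(df, as.data.frame(X))
  class(df) <- c("cohort", "data.frame")
  df
}

# Loop-based confusion oracle.
ref_confusion <- function(flag, y, w) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(y)) {
    if (flag[i] && y[i] == 1) tp <- tp + w[i]
    if (flag[i] && y[i] == 0) fp <- fp + w[i]
    if (!flag[i] && y[i] == 1) fn <- fn + w[i]
    if (!flag[i] && y[i] == 0) tn <- tn + w[i]
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Jaccard similarity of two condition sets given as "pred=level" strings.
condition_set <- function(conditions)
  paste(conditions$predictor, conditions$level, sep = "=")

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# --- synthetic annotated trees for pruning tests ------------------------- #

# Build a risk_tree object directly from a nested shape list whose elements
# are lists with `level` and optional `yes`/`no`. Counts are filled so that
# parents pool their children.
tree_from_shape <- function(shape) {
  nodes <- list()
  nid <- 0L
  build <- function(s, depth, path) {
    nid <<- nid + 1L
    id <- nid
    node <- list(node_id = id, split_predictor = NA_character_,
                 yes_child = NA_integer_, no_child = NA_integer_,
                 n_unweighted = 0L, weighted_n = 0,
                 weighted_prevalence = 0, depth = depth,
                 path_conditions = path, risk_level = s$level)
    nodes[[id]] <<- node
    if (!is.null(s$yes)) {
      pred <- sprintf("x%04d", depth + 1L)
      yes_id <- build(s$yes, depth + 1L,
                      rbind(path, data.frame(predictor = pred, level = "yes")))
      no_id <- build(s$no, depth + 1L,
                     rbind(path, data.frame(predictor = pred, level = "no")))
      nodes[[id]]$split_predictor <<- pred
      nodes[[id]]$yes_child <<- yes_id
      nodes[[id]]$no_child <<- no_id
      nodes[[id]]$n_unweighted <<- nodes[[yes_id]]$n_unweighted +
        nodes[[no_id]]$n_unweighted
      nodes[[id]]$weighted_n <<- nodes[[yes_id]]$weighted_n +
        nodes[[no_id]]$weighted_n
      wn <- nodes[[id]]$weighted_n
      nodes[[id]]$weighted_prevalence <<-
        (nodes[[yes_id]]$weighted_prevalence * nodes[[yes_id]]$weighted_n +
           nodes[[no_id]]$weighted_prevalence * nodes[[no_id]]$weighted_n) / wn
    } else {
      nodes[[id]]$n_unweighted <<- s$n
      nodes[[id]]$weighted_n <<- s$w
      nodes[[id]]$weighted_prevalence <<- s$prev
    }
    id
  }
  empty <- data.frame(predictor = character(0), level = character(0))
  root <- build(shape, 0L, empty)
  structure(list(nodes = nodes, root_id = root,
                 base_rate = nodes[[root]]$weighted_prevalence,
                 outcome = "y_primary", config = grow_config(n_min = 1)),
            class = "risk_tree")
}

# All binary tree shapes with exactly k internal nodes (Catalan enumeration).
all_shapes <- function(k) {
  if (k == 0) return(list(list()))
  out <- list()
  for (i in 0:(k - 1)) {
    for (l in all_shapes(i)) for (r in all_shapes(k - 1 - i))
      out[[length(out) + 1L]] <- list(yes = l, no = r)
  }
  out
}

count_shape_nodes <- function(s)
  if (is.null(s$yes)) 1L else
    1L + count_shape_nodes(s$yes) + count_shape_nodes(s$no)

# Assign risk levels (indexed preorder) to a shape, attaching leaf stats.
shape_with_levels <- function(s, levels, env = new.env()) {
  if (is.null(env$i)) env$i <- 0L
  env$i <- env$i + 1L
  node <- list(level = levels[env$i])
  if (!is.null(s$yes)) {
    node$yes <- shape_with_levels(s$yes, levels, env)
    node$no <- shape_with_levels(s$no, levels, env)
  } else {
    node$n <- 10L; node$w <- 10
    node$prev <- switch(node$level, high = 0.5, moderate = 0.12, low = 0.02)
  }
  node
}

# Independent minimal-terminal count: homogeneous-subtree collapses are
# confluent, so the minimum equals a direct recursive computation.
ref_min_terminals <- function(tree, id = tree$root_id) {
  levels_below <- function(i) {
    nd <- tree$nodes[[i]]
    if (is.na(nd$split_predictor)) return(nd$risk_level)
    unique(c(nd$risk_level, levels_below(nd$yes_child),
             levels_below(nd$no_child)))
  }
  nd <- tree$nodes[[id]]
  if (is.na(nd$split_predictor) || length(levels_below(id)) == 1L) return(1L)
  ref_min_terminals(tree, nd$yes_child) + ref_min_terminals(tree, nd$no_child)
}
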