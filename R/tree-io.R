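#' Serialize a tree to JSON and back
#'
#' Nodes are written flat, one object per node, with fields `node_id`,
#' `split_predictor`, `yes_child`, `no_child`, `n_unweighted`, `weighted_n`,
#' `weighted_prevalence`, `depth`, `path_conditions` and (when annotated)
#' `risk_level`. The round trip is stable: reading back a written tree
#' reproduces it.
#'
#' @param tree A `risk_tree`.
#' @param path File path of the JSON document.
#' @return `write_tree_json` returns `path` invisibly; `read_tree_json`
#'   returns the `risk_tree`.
#' @export
write_tree_json <- function(tree, path) {
  nodes <- lapply(live_nodes(tree), function(nd) {
    nd$path_conditions <- if (nrow(nd$path_conditions)) {
      lapply(seq_len(nrow(nd$path_conditions)), function(i)
        list(predictor = nd$path_conditions$predictor[i],
             level = nd$path_conditions$level[i]))
    } else list()
    nd
  })
  cfg <- unclass(tree$config)
  if (is.infinite(cfg$max_depth)) cfg$max_depth <- NULL  # null = unbounded
  doc <- list(format = "adversitree/tree", version = 1L,
              outcome = tree$outcome,
              base_rate = tree$base_rate,
              config = cfg,
              thresholds = if (is.null(tree$thresholds)) NULL else
                unclass(tree$thresholds),
              root_id = tree$root_id,
              nodes = unname(nodes))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- doc$config
  cfg$max_depth <- if (is.null(cfg$max_depth)) Inf else cfg$max_depth
  config <- grow_config(cfg$n_min, cfg$min_impurity_decrease, cfg$max_depth,
                        cfg$use_weights_in_splitting)
  nodes <- vector("list", max(vapply(doc$nodes, `[[`, integer(1), "node_id")))
  for (nd in doc$nodes) {
    pc <- if (length(nd$path_conditions)) {
      data.frame(
        predictor = vapply(nd$path_conditions, `[[`, character(1),
                           "predictor"),
        level = vapply(nd$path_conditions, `[[`, character(1), "level"))
    } else data.frame(predictor = character(0), level = character(0))
    node <- list(node_id = as.integer(nd$node_id),
                 split_predictor = if (is.null(nd$split_predictor))
                   NA_character_ else nd$split_predictor,
                 yes_child = if (is.null(nd$yes_child)) NA_integer_ else
                   as.integer(nd$yes_child),
                 no_child = if (is.null(nd$no_child)) NA_integer_ else
                   as.integer(nd$no_child),
                 n_unweighted = as.integer(nd$n_unweighted),
                 weighted_n = as.numeric(nd$weighted_n),
                 weighted_prevalence = as.numeric(nd$weighted_prevalence),
                 depth = as.integer(nd$depth),
                 path_conditions = pc)
    if (!is.null(nd$risk_level)) node$risk_level <- nd$risk_level
    nodes[[node$node_id]] <- node
  }
  tree <- structure(list(nodes = nodes,
                         root_id = as.integer(doc$root_id),
                         base_rate = as.numeric(doc$base_rate),
                         outcome = doc$outcome,
                         config = config),
                    class = "risk_tree")
  if (!is.null(doc$thresholds))
    tree$thresholds <- risk_thresholds(doc$thresholds$base_rate,
                                       doc$thresholds$high_multiplier,
                                       doc$thresholds$low_multiplier)
  tree
}
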