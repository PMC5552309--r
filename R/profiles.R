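#' Extract high-risk subgroup profiles from a pruned tree
#'
#' One profile per high-risk terminal: the ordered root-to-leaf path
#' conditions, the terminal's weighted training prevalence and its unweighted
#' size. Profiles are ordered by descending training prevalence and labelled
#' `subgroup_1`, `subgroup_2`, ... Conditions use the "no/missing" coding: a
#' `"no"` condition matches both true negatives and item non-response.
#'
#' @param tree An annotated (ideally pruned) `risk_tree`.
#' @return An object of class `subgroup_profiles`: a list of profiles, each
#'   with `profile_id`, `conditions` (data frame `predictor`, `level`),
#'   `training_prevalence`, `training_n` and `fires` (logical; profiles
#'   disabled by porting never match).
#' @export
extract_high_risk_profiles <- function(tree) {
  terms <- terminal_nodes(tree)
  high <- Filter(function(nd) {
    if (is.null(nd$risk_level))
      stop("tree is not annotated; run annotate_tree() first")
    nd$risk_level == "high"
  }, terms)
  ord <- order(vapply(high, `[[`, numeric(1), "weighted_prevalence"),
               decreasing = TRUE)
  profiles <- lapply(seq_along(ord), function(i) {
    nd <- high[[ord[i]]]
    list(profile_id = paste0("subgroup_", i),
         conditions = nd$path_conditions,
         training_prevalence = nd$weighted_prevalence,
         training_n = nd$n_unweighted,
         fires = TRUE)
  })
  structure(profiles, class = "subgroup_profiles")
}

#' Classify individuals as high risk by profile membership
#'
#' An individual is flagged high risk when at least one profile's conditions
#' all hold (`"yes"` requires the predictor at 1, `"no"` at 0). The matched
#' profile is the first satisfied one in stored (descending-prevalence)
#' order; on a training cohort the profiles come from disjoint leaves, so the
#' order is immaterial there.
#'
#' @param profiles A `subgroup_profiles` object.
#' @param cohort A `cohort` containing every predictor the conditions name.
#' @return A data frame of class `high_risk_classification` with columns
#'   `flag` (logical) and `profile_id` (character, `NA` when unflagged).
#' @export
classify_high_risk <- function(profiles, cohort) {
  n <- nrow(cohort)
  flag <- rep(FALSE, n)
  matched <- rep(NA_character_, n)
  for (pr in profiles) {
    if (!isTRUE(pr$fires)) next
    ok <- rep(TRUE, n)
    for (i in seq_len(nrow(pr$conditions))) {
      pred <- pr$conditions$predictor[i]
      if (!pred %in% names(cohort))
        stop("cohort lacks predictor '", pred, "' required by profile ",
             pr$profile_id)
      want <- if (pr$conditions$level[i] == "yes") 1L else 0L
      ok <- ok & (cohort[[pred]] == want)
    }
    newly <- ok & !flag
    matched[newly] <- pr$profile_id
    flag <- flag | ok
  }
  structure(data.frame(flag = flag, profile_id = matched,
                       stringsAsFactors = FALSE),
            class = c("high_risk_classification", "data.frame"))
}

#' Predictor mapping between discovery and validation cohorts
#'
#' Describes how each discovery predictor is harmonised to its closest proxy
#' in a second cohort: the target name (or `NA` when no appropriate
#' substitute exists), an optional per-variable proxy disagreement
#' probability used by [make_validation_cohort()], and a free-text note.
#'
#' @param source Unique discovery predictor names.
#' @param target Proxy names in the validation cohort; `NA` marks an absent
#'   variable. Defaults to `source` (identity mapping).
#' @param flip_prob Per-variable probability that the proxy disagrees with
#'   the latent value, in \[0, 0.5\] typically; recycled. Default 0.
#' @param note Free-text provenance notes; recycled.
#' @return A data frame of class `predictor_mapping`; attribute `coverage`
#'   holds the mapped fraction.
#' @export
predictor_mapping <- function(source, target = source, flip_prob = 0,
                              note = "") {
  if (anyDuplicated(source)) stop("mapping sources must be unique")
  flip_prob <- rep_len(flip_prob, length(source))
  if (any(flip_prob < 0 | flip_prob > 1))
    stop("'flip_prob' must lie in [0, 1]")
  m <- data.frame(source = as.character(source),
                  target = as.character(target),
                  flip_prob = flip_prob,
                  note = rep_len(as.character(note), length(source)),
                  stringsAsFactors = FALSE)
  attr(m, "coverage") <- mean(!is.na(m$target))
  class(m) <- c("predictor_mapping", "data.frame")
  m
}

as_predictor_mapping <- function(m) {
  if (inherits(m, "predictor_mapping")) return(m)
  if (is.data.frame(m) && all(c("source", "target") %in% names(m)))
    return(predictor_mapping(m$source, m$target,
                             if ("flip_prob" %in% names(m)) m$flip_prob else 0,
                             if ("note" %in% names(m)) m$note else ""))
  stop("'mapping' must be a predictor_mapping or a data frame with ",
       "columns source/target")
}

#' Read / write a predictor mapping as CSV
#'
#' Columns `source,target,flip_prob,note`; an empty target marks an absent
#' variable.
#'
#' @param mapping A [predictor_mapping()].
#' @param path File path.
#' @return `read_mapping_csv` returns a `predictor_mapping`;
#'   `write_mapping_csv` returns `path` invisibly.
#' @export
write_mapping_csv <- function(mapping, path) {
  m <- as.data.frame(mapping)
  m$target[is.na(m$target)] <- ""
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping_csv
#' @export
read_mapping_csv <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(source = "character",
                                      target = "character"))
  m$target[!nzchar(m$target)] <- NA_character_
  as_predictor_mapping(m)
}

#' Port subgroup profiles to a validation cohort
#'
#' Renames every condition's predictor to its mapped proxy. Conditions on
#' variables without a substitute are handled per `policy`:
#' `"never-fires"` (default) disables the whole profile, so nobody is
#' classified high risk on unverifiable conditions; `"drop-condition"`
#' removes the condition and keeps the (now broader) profile, the
#' closest-proxy-and-carry-on behaviour; `"fail"` stops with an error.
#'
#' @param profiles A `subgroup_profiles` object.
#' @param mapping A [predictor_mapping()].
#' @param policy One of `"never-fires"`, `"drop-condition"`, `"fail"`.
#' @return The ported `subgroup_profiles`; attribute `"coverage_report"` is a
#'   data frame with one row per profile: number of conditions, number
#'   mapped, mapped fraction, dropped conditions and whether the profile can
#'   still fire.
#' @export
port_profiles <- function(profiles, mapping,
                          policy = c("never-fires", "drop-condition",
                                     "fail")) {
  policy <- match.arg(policy)
  mapping <- as_predictor_mapping(mapping)
  report <- data.frame(profile_id = character(0), n_conditions = integer(0),
                       n_mapped = integer(0), mapped_fraction = numeric(0),
                       dropped = character(0), fires = logical(0),
                       stringsAsFactors = FALSE)
  ported <- lapply(profiles, function(pr) {
    conds <- pr$conditions
    idx <- match(conds$predictor, mapping$source)
    if (anyNA(idx))
      stop("mapping lacks source predictor(s): ",
           paste(conds$predictor[is.na(idx)], collapse = ", "))
    tgt <- mapping$target[idx]
    absent <- is.na(tgt)
    dropped <- character(0)
    fires <- isTRUE(pr$fires)
    if (any(absent)) {
      if (policy == "fail")
        stop("profile ", pr$profile_id, " uses unmapped predictor(s): ",
             paste(conds$predictor[absent], collapse = ", "))
      dropped <- conds$predictor[absent]
      if (policy == "never-fires") fires <- FALSE
    }
    new_conds <- conds[!absent, , drop = FALSE]
    new_conds$predictor <- tgt[!absent]
    rownames(new_conds) <- NULL
    report <<- rbind(report, data.frame(
      profile_id = pr$profile_id,
      n_conditions = nrow(conds),
      n_mapped = sum(!absent),
      mapped_fraction = sum(!absent) / nrow(conds),
      dropped = paste(dropped, collapse = ";"),
      fires = fires, stringsAsFactors = FALSE))
    pr$conditions <- if (policy == "drop-condition") new_conds else {
      tmp <- conds; tmp$predictor[!absent] <- tgt[!absent]; tmp
    }
    pr$fires <- fires
    pr
  })
  structure(ported, class = "subgroup_profiles",
            coverage_report = report)
}

#' Serialize subgroup profiles to JSON and back
#'
#' @param profiles A `subgroup_profiles` object.
#' @param path File path.
#' @return `write_profiles_json` returns `path` invisibly;
#'   `read_profiles_json` returns the `subgroup_profiles`.
#' @export
write_profiles_json <- function(profiles, path) {
  doc <- lapply(profiles, function(pr)
    list(profile_id = pr$profile_id,
         conditions = lapply(seq_len(nrow(pr$conditions)), function(i)
           list(predictor = pr$conditions$predictor[i],
                level = pr$conditions$level[i])),
         training_prevalence = pr$training_prevalence,
         training_n = pr$training_n,
         fires = pr$fires))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_profiles_json
#' @export
read_profiles_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  profiles <- lapply(doc, function(pr)
    list(profile_id = pr$profile_id,
         conditions = data.frame(
           predictor = vapply(pr$conditions, `[[`, character(1), "predictor"),
           level = vapply(pr$conditions, `[[`, character(1), "level"),
           stringsAsFactors = FALSE),
         training_prevalence = as.numeric(pr$training_prevalence),
         training_n = as.integer(pr$training_n),
         fires = isTRUE(pr$fires)))
  structure(profiles, class = "subgroup_profiles")
}

#' @export
print.subgroup_profiles <- function(x, ...) {
  cat(length(x), "high-risk subgroup profile(s)\n")
  for (pr in x) {
    cat(sprintf("%s: prevalence %.1f%%, n = %d%s\n", pr$profile_id,
                100 * pr$training_prevalence, pr$training_n,
                if (isTRUE(pr$fires)) "" else " [disabled]"))
    if (nrow(pr$conditions))
      cat(paste0("  - ", pr$conditions$predictor, " = ",
                 pr$conditions$level, collapse = "\n"), "\n")
  }
  invisible(x)
}
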