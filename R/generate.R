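#' Generate a synthetic discovery cohort
#'
#' Draws a cohort under the supplied [cohort_spec()]: correlated binary
#' predictors from a shared latent adversity factor, item missingness folded
#' into the "no/missing" level, gamma survey weights with mean 1, a binary
#' primary outcome whose prevalence is the planted value inside each subgroup
#' and a background rate calibrated so the overall weighted prevalence hits
#' `base_prevalence`, and six secondary outcomes sharing the latent factor
#' and subgroup membership.
#'
#' Planted-subgroup membership is resolved in declared order (first match
#' wins). The realized membership vector is attached as attribute
#' `"planted_membership"` (0 = background) and the latent factor as
#' `"latent_factor"`; both are generator ground truth for recovery studies,
#' not observable data.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` of class `cohort` with columns `id`, `weight`,
#'   `y_primary`, `y_sec1`..`y_sec6` and the predictor columns `x0001`...
#' @section Errors: if the planted subgroups are so large or extreme that the
#'   background rate needed to reach `base_prevalence` falls outside
#'   \[0, 1\], generation stops with a calibration error.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  draw_cohort(spec)
}

# Core draw; assumes the RNG state is already set. Split out so the
# validation-cohort generator can continue the stream for proxy noise.
draw_cohort <- function(spec) {
  n <- spec$n_individuals
  p <- spec$n_predictors
  pred_names <- predictor_labels(p)

  z <- stats::rnorm(n)
  lam <- sqrt(spec$clustering_strength)
  res <- sqrt(1 - spec$clustering_strength)
  X <- matrix(0L, n, p, dimnames = list(NULL, pred_names))
  thr <- stats::qnorm(spec$predictor_marginals)
  for (j in seq_len(p)) {
    u <- lam * z + res * stats::rnorm(n)
    xj <- as.integer(u < thr[j])
    mr <- spec$missingness_rates[j]
    if (mr > 0) xj <- xj * as.integer(stats::runif(n) >= mr)
    X[, j] <- xj
  }

  w <- if (spec$weight_dispersion > 0) {
    d2 <- spec$weight_dispersion^2
    stats::rgamma(n, shape = 1 / d2, scale = d2)
  } else rep(1, n)

  membership <- subgroup_membership(X, spec$planted_subgroups)
  prev_in <- vapply(spec$planted_subgroups, `[[`, numeric(1), "prevalence")

  w_tot <- sum(w)
  w_planted <- 0
  if (length(prev_in))
    w_planted <- sum(vapply(seq_along(prev_in), function(g)
      prev_in[g] * sum(w[membership == g]), numeric(1)))
  w_bg <- sum(w[membership == 0L])
  pr <- numeric(n)
  if (w_bg > 0) {
    q <- (spec$base_prevalence * w_tot - w_planted) / w_bg
    if (q < 0 || q > 1)
      stop("calibration infeasible: planted subgroups imply a background ",
           "outcome rate of ", signif(q, 4), ", outside [0, 1]")
    pr[membership == 0L] <- q
  }
  if (length(prev_in))
    pr[membership > 0L] <- prev_in[membership[membership > 0L]]
  y <- stats::rbinom(n, 1L, pr)

  member <- as.numeric(membership > 0L)
  ysec <- matrix(0L, n, 6L)
  for (k in 1:6) {
    lp <- spec$secondary_loading[k] * z + spec$secondary_member_bump[k] * member
    target <- spec$secondary_prevalences[k]
    alpha <- stats::uniroot(function(a)
      stats::weighted.mean(stats::plogis(a + lp), w) - target,
      lower = -30, upper = 30)$root
    ysec[, k] <- stats::rbinom(n, 1L, stats::plogis(alpha + lp))
  }

  cohort <- data.frame(id = sprintf("id%07d", seq_len(n)),
                       weight = w, y_primary = y)
  colnames(ysec) <- paste0("y_sec", 1:6)
  cohort <- cbind(cohort, as.data.frame(ysec), as.data.frame(X))
  class(cohort) <- c("cohort", "data.frame")
  attr(cohort, "planted_membership") <- membership
  attr(cohort, "latent_factor") <- z
  cohort
}

subgroup_membership <- function(X, subgroups) {
  n <- nrow(X)
  membership <- integer(n)
  for (g in seq_along(subgroups)) {
    sg <- subgroups[[g]]
    ok <- rep(TRUE, n)
    for (i in seq_along(sg$predictors))
      ok <- ok & (X[, sg$predictors[i]] == sg$conditions[i])
    membership[membership == 0L & ok] <- g
  }
  membership
}

#' Predictor columns of a cohort
#'
#' @param cohort A `cohort` data frame.
#' @return Character vector of predictor column names (`x`-prefixed).
#' @export
predictor_columns <- function(cohort) {
  grep("^x[0-9]+$", names(cohort), value = TRUE)
}

#' Encode a raw three-level predictor table to the modelling coding
#'
#' Dichotomized predictors keep item non-response: "yes" maps to 1, both
#' "no" and "missing" map to 0 ("no/missing").
#'
#' @param raw_table Matrix or data frame whose entries are `"yes"`, `"no"`
#'   or `"missing"`.
#' @return Integer matrix of the same shape with entries in `{0, 1}`.
#' @export
encode_predictors <- function(raw_table) {
  m <- as.matrix(raw_table)
  bad <- which(!(m %in% c("yes", "no", "missing")))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop("unrecognized predictor level '", m[bad[1]], "' at row ", i,
         ", column ", if (is.null(colnames(m))) j else colnames(m)[j])
  }
  out <- matrix(as.integer(m == "yes"), nrow(m), ncol(m),
                dimnames = dimnames(m))
  out
}

#' Generate an external validation cohort through a predictor mapping
#'
#' Draws a second cohort with the same statistical structure as the discovery
#' generator (new individuals from a seed derived from the spec's), then
#' degrades it the way closest-proxy harmonisation between two surveys does:
#' each mapped predictor is observed through a noisy proxy that flips the
#' latent value independently with the mapping's per-variable
#' `flip_prob`, unmapped predictors are absent from the output, and mapped
#' predictors are renamed to their target labels. Planted subgroups and the
#' outcome are generated from the latent (pre-noise) predictors, so profile
#' classification of the observed table degrades as proxy noise grows.
#'
#' @param spec A [cohort_spec()] (the discovery spec).
#' @param mapping A [predictor_mapping()]; sources must be predictors of
#'   `spec`.
#' @return A `cohort` with the mapped predictor columns only. Attributes:
#'   `"planted_membership"`, `"latent_factor"` (ground truth) and
#'   `"coverage"` (the mapping coverage report, one row per source).
#' @export
make_validation_cohort <- function(spec, mapping) {
  stopifnot(inherits(spec, "cohort_spec"))
  mapping <- as_predictor_mapping(mapping)
  pred_names <- predictor_labels(spec$n_predictors)
  unknown <- setdiff(mapping$source, pred_names)
  if (length(unknown))
    stop("mapping references unknown predictor(s): ",
         paste(unknown, collapse = ", "))

  seed2 <- (spec$seed + 1000003L) %% 2147483587L
  set.seed(seed2)
  cohort <- draw_cohort(spec)

  mapped <- mapping[!is.na(mapping$target), , drop = FALSE]
  n <- nrow(cohort)
  for (i in seq_len(nrow(mapped))) {
    fp <- mapped$flip_prob[i]
    if (fp > 0) {
      col <- mapped$source[i]
      flip <- stats::runif(n) < fp
      cohort[[col]] <- as.integer(xor(cohort[[col]] == 1L, flip))
    }
  }

  keep_meta <- setdiff(names(cohort), pred_names)
  out <- cohort[, c(keep_meta, mapped$source), drop = FALSE]
  names(out)[match(mapped$source, names(out))] <- mapped$target
  class(out) <- c("cohort", "data.frame")
  attr(out, "planted_membership") <- attr(cohort, "planted_membership")
  attr(out, "latent_factor") <- attr(cohort, "latent_factor")
  attr(out, "coverage") <- data.frame(
    source = mapping$source,
    target = ifelse(is.na(mapping$target), NA_character_, mapping$target),
    mapped = !is.na(mapping$target),
    flip_prob = mapping$flip_prob,
    stringsAsFactors = FALSE)
  out
}

#' Read / write a cohort as CSV
#'
#' The on-disk dialect is one header row and columns `id`, `weight`,
#' `y_primary`, `y_sec1`..`y_sec6`, `x0001`..; outcome and predictor entries
#' are strictly 0/1.
#'
#' @param cohort A `cohort` data frame.
#' @param path File path.
#' @return `read_cohort_csv` returns a validated `cohort`;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
}

validate_cohort <- function(cohort, require_secondary = FALSE) {
  need <- c("id", "weight", "y_primary")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (require_secondary) {
    sec <- paste0("y_sec", 1:6)
    missing_cols <- setdiff(sec, names(cohort))
    if (length(missing_cols))
      stop("cohort lacks secondary outcome column(s): ",
           paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cohort$id)) stop("cohort ids must be unique")
  if (any(cohort$weight < 0) || sum(cohort$weight) <= 0)
    stop("weights must be non-negative with positive total")
  binary_cols <- c(grep("^y_", names(cohort), value = TRUE),
                   grep("^x[0-9]+$", names(cohort), value = TRUE))
  for (col in binary_cols)
    if (!all(cohort[[col]] %in% c(0L, 1L)))
      stop("column '", col, "' is not strictly 0/1")
  class(cohort) <- unique(c("cohort", class(cohort)))
  cohort
}
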