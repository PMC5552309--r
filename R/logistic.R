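#' Stepwise-selection configuration
#'
#' @param entry_alpha Significance threshold a candidate's Wald p-value must
#'   beat to enter the model (default 0.05).
#' @param stay_alpha Threshold above which an included term is removed
#'   (default 0.05).
#' @param max_iterations Cap on selection steps (default 100).
#' @param convergence_tol IRLS convergence tolerance passed to the fitter
#'   (default 1e-8).
#' @param classification_threshold Fitted-probability cut-off used by
#'   [classify_by_probability()] (default 0.5).
#' @return An object of class `stepwise_config`.
#' @export
stepwise_config <- function(entry_alpha = 0.05, stay_alpha = 0.05,
                            max_iterations = 100L, convergence_tol = 1e-8,
                            classification_threshold = 0.5) {
  if (entry_alpha <= 0 || entry_alpha >= 1 ||
      stay_alpha <= 0 || stay_alpha >= 1)
    stop("alphas must lie in (0, 1)")
  structure(list(entry_alpha = entry_alpha, stay_alpha = stay_alpha,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 classification_threshold = classification_threshold),
            class = "stepwise_config")
}

#' Weighted logistic regression fit
#'
#' Maximum-likelihood logistic regression of a binary outcome on a subset of
#' binary predictors, with survey weights treated as frequency-style case
#' weights (the estimating equations of weighted ML). Fitting is by
#' iteratively reweighted least squares via [stats::glm()]. Separation and
#' non-convergence are detected and reported on the returned object rather
#' than silently ignored.
#'
#' @param cohort A `cohort` (or data frame with the needed columns).
#' @param predictors Character vector of predictor columns; may be empty for
#'   an intercept-only model.
#' @param outcome Outcome column (default `"y_primary"`).
#' @param weights Weights vector; defaults to `cohort$weight`, or unit
#'   weights when absent.
#' @param convergence_tol IRLS tolerance (default 1e-8).
#' @return An object of class `logistic_model`: coefficients, standard
#'   errors, Wald z and p-values, odds ratios with 95% intervals, fitted
#'   probabilities, and flags `converged` / `separation`.
#' @export
fit_logistic <- function(cohort, predictors, outcome = "y_primary",
                         weights = NULL, convergence_tol = 1e-8) {
  if (is.null(weights))
    weights <- if ("weight" %in% names(cohort)) cohort$weight else
      rep(1, nrow(cohort))
  y <- cohort[[outcome]]
  if (nrow(cohort) <= length(predictors) + 1L)
    stop("more parameters than observations")
  for (p in predictors)
    if (length(unique(cohort[[p]])) < 2L)
      stop("predictor '", p, "' is constant; drop it before fitting")
  dat <- cbind(data.frame(.y = y), cohort[, predictors, drop = FALSE])
  fml <- if (length(predictors))
    stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  else stats::as.formula(".y ~ 1")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = dat,
               weights = weights,
               control = stats::glm.control(epsilon = convergence_tol,
                                            maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      # non-integer #successes warnings are expected under survey weights
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  rn <- rownames(sm)
  coefs <- stats::setNames(sm[, "Estimate"], rn)
  se <- stats::setNames(sm[, "Std. Error"], rn)
  zq <- stats::qnorm(0.975)
  structure(list(
    predictors = predictors,
    coefficients = coefs,
    se = se,
    z = stats::setNames(sm[, "z value"], rn),
    p = stats::setNames(sm[, "Pr(>|z|)"], rn),
    odds_ratios = exp(coefs),
    or_lower = exp(coefs - zq * se),
    or_upper = exp(coefs + zq * se),
    fitted = as.numeric(stats::fitted(fit)),
    outcome = outcome,
    converged = fit$converged,
    separation = separation),
    class = "logistic_model")
}

#' Stepwise logistic-regression selection
#'
#' Classical forward-backward stepwise selection driven by Wald p-values:
#' repeatedly enter the candidate with the smallest p-value below
#' `entry_alpha`, then remove any included term whose p-value exceeds
#' `stay_alpha`. Revisiting a previously seen model state stops the loop
#' (anti-cycling), so the procedure terminates. The full selection trace is
#' attached to the returned model.
#'
#' @param cohort A `cohort`.
#' @param candidates Candidate predictor columns (default: all predictors).
#' @param outcome Outcome column (default `"y_primary"`).
#' @param config A [stepwise_config()].
#' @return A `logistic_model` for the final selected terms, with attribute
#'   `"trace"` (data frame of step, action, variable, p-value).
#' @export
stepwise_select <- function(cohort, candidates = predictor_columns(cohort),
                            outcome = "y_primary",
                            config = stepwise_config()) {
  candidates <- candidates[vapply(candidates, function(p)
    length(unique(cohort[[p]])) > 1L, logical(1))]
  selected <- character(0)
  trace <- data.frame(step = integer(0), action = character(0),
                      variable = character(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  seen <- character(0)
  step_no <- 0L
  wald_p <- function(model, term) unname(model$p[term])
  repeat {
    step_no <- step_no + 1L
    if (step_no > config$max_iterations) break
    state <- paste(sort(selected), collapse = "|")
    if (state %in% seen) break
    seen <- c(seen, state)

    pool <- setdiff(candidates, selected)
    entered <- FALSE
    if (length(pool)) {
      pvals <- vapply(pool, function(cand) {
        m <- fit_logistic(cohort, c(selected, cand), outcome,
                          convergence_tol = config$convergence_tol)
        wald_p(m, cand)
      }, numeric(1))
      best <- which.min(pvals)
      if (pvals[best] < config$entry_alpha) {
        selected <- c(selected, pool[best])
        trace <- rbind(trace, data.frame(step = step_no, action = "enter",
                                         variable = pool[best],
                                         p_value = pvals[best]))
        entered <- TRUE
      }
    }
    # backward sweep on the current model
    removed <- FALSE
    repeat {
      if (!length(selected)) break
      m <- fit_logistic(cohort, selected, outcome,
                        convergence_tol = config$convergence_tol)
      ps <- vapply(selected, function(v) wald_p(m, v), numeric(1))
      worst <- which.max(ps)
      if (ps[worst] > config$stay_alpha) {
        trace <- rbind(trace, data.frame(step = step_no, action = "remove",
                                         variable = selected[worst],
                                         p_value = ps[worst]))
        selected <- selected[-worst]
        removed <- TRUE
      } else break
    }
    if (!entered && !removed) break
  }
  model <- fit_logistic(cohort, selected, outcome,
                        convergence_tol = config$convergence_tol)
  attr(model, "trace") <- trace
  model
}

predict_logistic <- function(model, cohort) {
  eta <- rep(model$coefficients[["(Intercept)"]], nrow(cohort))
  for (p in model$predictors)
    eta <- eta + model$coefficients[[p]] * cohort[[p]]
  stats::plogis(eta)
}

#' Classify individuals by fitted probability
#'
#' Flags an individual high risk when the model's fitted probability strictly
#' exceeds the threshold; the result feeds the diagnostics module exactly
#' like a profile-based classification.
#'
#' @param model A `logistic_model`.
#' @param cohort A `cohort` carrying the model's predictors.
#' @param threshold Probability cut-off (default 0.5).
#' @return A `high_risk_classification` data frame.
#' @export
classify_by_probability <- function(model, cohort, threshold = 0.5) {
  prob <- predict_logistic(model, cohort)
  structure(data.frame(flag = prob > threshold,
                       profile_id = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("high_risk_classification", "data.frame"))
}

#' Sensitivity/specificity sweep over probability thresholds
#'
#' @param model A `logistic_model`.
#' @param cohort A `cohort`.
#' @param outcome Outcome column (default the model's).
#' @param thresholds Cut-offs to evaluate; default: every distinct fitted
#'   probability plus 0 and 1.
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity` (weighted estimates).
#' @export
threshold_sweep <- function(model, cohort, outcome = model$outcome,
                            thresholds = NULL) {
  prob <- predict_logistic(model, cohort)
  if (is.null(thresholds))
    thresholds <- sort(unique(c(0, prob, 1)))
  y <- cohort[[outcome]]
  w <- if ("weight" %in% names(cohort)) cohort$weight else rep(1, nrow(cohort))
  out <- lapply(thresholds, function(t) {
    ct <- confusion_table(prob > t, y, w)
    data.frame(threshold = t,
               sensitivity = if (ct$tp + ct$fn > 0)
                 ct$tp / (ct$tp + ct$fn) else NA_real_,
               specificity = if (ct$tn + ct$fp > 0)
                 ct$tn / (ct$tn + ct$fp) else NA_real_)
  })
  do.call(rbind, out)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Weighted logistic model (", length(x$predictors), " predictor(s))\n",
      sep = "")
  tab <- data.frame(coef = x$coefficients, se = x$se, p = x$p,
                    OR = x$odds_ratios, lo = x$or_lower, hi = x$or_upper)
  print(round(tab, 4))
  if (!x$converged) cat("WARNING: IRLS did not converge\n")
  if (x$separation) cat("WARNING: quasi-separation detected\n")
  invisible(x)
}
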