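#' Weighted and unweighted confusion table
#'
#' Cross-tabulates the high-risk flag against an observed binary outcome,
#' keeping both survey-weighted cell totals (`tp`, `fp`, `fn`, `tn`) and
#' unweighted head counts (`tp_u`, ...).
#'
#' @param classification A `high_risk_classification`, or a logical/0-1
#'   vector of flags.
#' @param outcome Binary 0/1 vector.
#' @param weights Non-negative weights; default all 1.
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(classification, outcome,
                            weights = rep(1, length(outcome))) {
  flag <- if (inherits(classification, "high_risk_classification"))
    classification$flag else as.logical(classification)
  if (length(flag) != length(outcome) || length(outcome) != length(weights))
    stop("'classification', 'outcome' and 'weights' must have equal length")
  pos <- outcome == 1L
  structure(list(
    tp = sum(weights[flag & pos]), fp = sum(weights[flag & !pos]),
    fn = sum(weights[!flag & pos]), tn = sum(weights[!flag & !pos]),
    tp_u = sum(flag & pos), fp_u = sum(flag & !pos),
    fn_u = sum(!flag & pos), tn_u = sum(!flag & !pos)),
    class = "confusion_table")
}

proportion_ci <- function(p, n, method, level = 0.95) {
  if (n <= 0 || is.na(p)) return(c(NA_real_, NA_real_))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- zq * sqrt(p * (1 - p) / n)
    ci <- c(p - half, p + half)
  } else {  # wilson
    denom <- 1 + zq^2 / n
    centre <- (p + zq^2 / (2 * n)) / denom
    half <- zq * sqrt(p * (1 - p) / n + zq^2 / (4 * n^2)) / denom
    ci <- c(centre - half, centre + half)
  }
  pmin(pmax(ci, 0), 1)
}

#' Screening diagnostics from a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, computed on
#' the weighted cells. 95% confidence intervals use the stated method on the
#' relevant margin's unweighted size (a design-effect adjustment is out of
#' scope and the unweighted-margin choice is recorded in the output). A zero
#' margin yields an `NA` estimate flagged `undefined`, never a silent 0.
#'
#' @param table A [confusion_table()].
#' @param ci_method `"wald"` (normal approximation, default) or `"wilson"`.
#' @param level Confidence level (default 0.95).
#' @return A data frame of class `diagnostic_result` with columns `metric`,
#'   `estimate`, `lower`, `upper`, `n_margin`, `undefined`.
#' @examples
#' ct <- confusion_table(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' screening_metrics(ct)
#' @export
screening_metrics <- function(table, ci_method = c("wald", "wilson"),
                              level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  ci_method <- match.arg(ci_method)
  cells <- list(
    sensitivity = c(table$tp, table$fn, table$tp_u + table$fn_u),
    specificity = c(table$tn, table$fp, table$tn_u + table$fp_u),
    ppv = c(table$tp, table$fp, table$tp_u + table$fp_u),
    npv = c(table$tn, table$fn, table$tn_u + table$fn_u))
  rows <- lapply(names(cells), function(m) {
    num <- cells[[m]][1]; other <- cells[[m]][2]; n_u <- cells[[m]][3]
    undefined <- (num + other) <= 0 || n_u <= 0
    est <- if (undefined) NA_real_ else num / (num + other)
    ci <- if (undefined) c(NA_real_, NA_real_) else
      proportion_ci(est, n_u, ci_method, level)
    data.frame(metric = m, estimate = est, lower = ci[1], upper = ci[2],
               n_margin = n_u, undefined = undefined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ci_method") <- ci_method
  attr(out, "ci_margin") <- "unweighted"
  class(out) <- c("diagnostic_result", "data.frame")
  out
}

#' Evaluate one classification against the primary and secondary outcomes
#'
#' Applies the same high-risk classification to the primary outcome and the
#' six secondary outcomes (multifinality assessment): one set of screening
#' metrics per outcome, in the fixed report order antisocial behaviour,
#' substance misuse, poor physical health, poor mental health, risky health
#' behaviours, poor academic performance after the primary outcome.
#'
#' @param classification A `high_risk_classification` aligned with `cohort`.
#' @param cohort A `cohort` carrying `y_primary` and `y_sec1`..`y_sec6`.
#' @param ci_method,level Passed to [screening_metrics()].
#' @return A data frame of class `diagnostic_report`: one row per outcome and
#'   metric with `estimate`, `lower`, `upper`.
#' @export
evaluate_all_outcomes <- function(classification, cohort,
                                  ci_method = c("wald", "wilson"),
                                  level = 0.95) {
  ci_method <- match.arg(ci_method)
  cols <- c(y_primary = "suicidal_thoughts",
            y_sec1 = "antisocial_behaviour",
            y_sec2 = "substance_misuse",
            y_sec3 = "poor_physical_health",
            y_sec4 = "poor_mental_health",
            y_sec5 = "risky_health_behaviours",
            y_sec6 = "poor_academic_performance")
  missing_cols <- setdiff(names(cols), names(cohort))
  if (length(missing_cols))
    stop("cohort lacks outcome column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- do.call(rbind, lapply(names(cols), function(col) {
    ct <- confusion_table(classification, cohort[[col]], cohort$weight)
    sm <- screening_metrics(ct, ci_method, level)
    cbind(data.frame(outcome = cols[[col]], stringsAsFactors = FALSE),
          as.data.frame(sm))
  }))
  rownames(out) <- NULL
  class(out) <- c("diagnostic_report", "data.frame")
  out
}

#' @export
print.diagnostic_result <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    if (x$undefined[i]) {
      cat(sprintf("%-12s undefined (zero margin)\n", x$metric[i]))
    } else {
      cat(sprintf("%-12s %5.1f%% (95%% CI %.1f, %.1f)\n", x$metric[i],
                  100 * x$estimate[i], 100 * x$lower[i], 100 * x$upper[i]))
    }
  }
  invisible(x)
}
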