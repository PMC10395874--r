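# Confusion-matrix performance metrics with continuity-corrected Wilson
# confidence intervals, rank-based AUROC, and the reproducibility comparison
# used for external validation.

#' Binomial proportion with continuity-corrected Wilson 95% CI
#'
#' Point estimate and Wilson score interval with continuity correction, the
#' one-sample interval of `stats::prop.test()`. Bounds are clipped to
#' [0, 1]; everything is returned in percent.
#'
#' @param successes number of successes.
#' @param n number of trials (>= 1).
#' @param confidence confidence level (default 0.95).
#' @return named numeric vector `c(estimate, lower, upper)` in percent.
#' @export
proportion_ci <- function(successes, n, confidence = 0.95) {
  if (length(n) != 1 || n < 1)
    stop("precondition error: n must be >= 1", call. = FALSE)
  if (successes < 0 || successes > n)
    stop("precondition error: successes must lie in [0, n]", call. = FALSE)
  # the chi-square-approximation warning concerns the test statistic, not
  # the interval extracted here
  ci <- suppressWarnings(
    stats::prop.test(successes, n, conf.level = confidence,
                     correct = TRUE))$conf.int
  c(estimate = 100 * successes / n, lower = 100 * ci[1], upper = 100 * ci[2])
}

#' Confusion matrix from high-risk classification and outcome
#'
#' @param high logical/binary vector: classified high risk.
#' @param outcome binary outcome vector.
#' @return list of class `fn_confusion` with counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(high, outcome) {
  stopifnot(length(high) == length(outcome))
  high <- as.logical(high)
  y <- outcome == 1
  structure(list(tp = sum(high & y), tn = sum(!high & !y),
                 fp = sum(high & !y), fn = sum(!high & y)),
            class = "fn_confusion")
}

#' Diagnostic performance of a confusion matrix
#'
#' Sensitivity, specificity, PPV and NPV, each with its continuity-corrected
#' Wilson 95% CI (all in percent), plus the low-risk count (TN + FN) and the
#' outcome count. A predictive value with a zero denominator is reported as
#' `NA` (not applicable), never as 0.
#'
#' @param confusion `fn_confusion` or a list/vector with `tp`, `tn`, `fp`,
#'   `fn`.
#' @param auroc optional AUROC to carry along in the report.
#' @return object of class `fn_performance`: data frame `metrics` (metric,
#'   estimate, lower, upper), `low_risk` count and proportion (percent),
#'   `outcome` count and proportion, the counts, and optional `auroc`.
#' @export
performance <- function(confusion, auroc = NULL) {
  cm <- as.list(confusion)
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn_ <- cm$fn
  if (any(c(tp, tn, fp, fn_) < 0))
    stop("precondition error: negative confusion counts", call. = FALSE)
  if (tp + fn_ < 1 || tn + fp < 1)
    stop("precondition error: both outcome classes must be present",
         call. = FALSE)
  n <- tp + tn + fp + fn_
  row <- function(metric, x, d) {
    if (d == 0) return(data.frame(metric = metric, estimate = NA_real_,
                                  lower = NA_real_, upper = NA_real_))
    ci <- proportion_ci(x, d)
    data.frame(metric = metric, estimate = ci[["estimate"]],
               lower = ci[["lower"]], upper = ci[["upper"]])
  }
  metrics <- rbind(row("sensitivity", tp, tp + fn_),
                   row("specificity", tn, tn + fp),
                   row("ppv", tp, tp + fp),
                   row("npv", tn, tn + fn_))
  structure(list(metrics = metrics,
                 low_risk = tn + fn_, low_risk_pct = 100 * (tn + fn_) / n,
                 outcome = tp + fn_, outcome_pct = 100 * (tp + fn_) / n,
                 counts = c(tp = tp, tn = tn, fp = fp, fn = fn_),
                 auroc = auroc),
            class = "fn_performance")
}

#' @export
print.fn_performance <- function(x, ...) {
  cm <- x$counts
  cat(sprintf("TP %d  TN %d  FP %d  FN %d | outcome %d (%.1f%%), low risk %d (%.1f%%)\n",
              cm["tp"], cm["tn"], cm["fp"], cm["fn"],
              x$outcome, x$outcome_pct, x$low_risk, x$low_risk_pct))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i]))
      cat(sprintf("  %-12s not applicable\n", m$metric[i]))
    else
      cat(sprintf("  %-12s %5.1f (%.1f-%.1f)\n", m$metric[i],
                  m$estimate[i], m$lower[i], m$upper[i]))
  }
  if (!is.null(x$auroc)) cat(sprintf("  AUROC %.3f\n", x$auroc))
  invisible(x)
}

#' Area under the ROC curve (concordance probability)
#'
#' Rank-statistic formulation with ties counted one half via midranks;
#' equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores (higher = higher risk).
#' @param outcome binary outcome vector.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, outcome) {
  y <- outcome == 1
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0)
    stop("precondition error: both outcome classes required for AUROC",
         call. = FALSE)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sample test of equal proportions
#'
#' Continuity-corrected chi-square test of equal proportions (the two-sample
#' behavior of `stats::prop.test()`), two-tailed.
#'
#' @param x1,n1 successes and trials in the first sample.
#' @param x2,n2 successes and trials in the second sample.
#' @return two-tailed p-value.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1)
    stop("precondition error: both sample sizes must be >= 1", call. = FALSE)
  suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE)$p.value
  )
}

#' Reproducibility verdict for an externally validated CDR
#'
#' A published CDR counts as reproducible for a metric (sensitivity or
#' specificity) if the two-proportion test between its derivation-dataset
#' (DD) counts and this cohort's validation counts is non-significant for
#' the full validation dataset (VD) or for the restricted one (rVD).
#' Missing DD counts yield `"not_assessable"`, never a silent pass.
#'
#' @param dd published derivation-dataset confusion counts (`fn_confusion`
#'   or list with tp/tn/fp/fn), or `NULL` when unavailable.
#' @param vd validation-dataset confusion counts.
#' @param rvd optional restricted-validation-dataset confusion counts.
#' @param alpha significance level (default 0.05).
#' @return list with `sensitivity` and `specificity` (`TRUE`, `FALSE` or
#'   `NA`), p-values per comparison, and `overall`: one of `"both"`,
#'   `"sensitivity_only"`, `"specificity_only"`, `"neither"`,
#'   `"not_assessable"`.
#' @export
reproducibility_verdict <- function(dd, vd, rvd = NULL, alpha = 0.05) {
  if (is.null(dd) || any(is.na(unlist(dd[c("tp", "tn", "fp", "fn")])))) {
    return(list(sensitivity = NA, specificity = NA, p_values = NULL,
                overall = "not_assessable"))
  }
  dd <- as.list(dd); vd <- as.list(vd)
  cmp <- function(metric, a, b) {
    if (metric == "sensitivity")
      two_proportion_test(a$tp, a$tp + a$fn, b$tp, b$tp + b$fn)
    else
      two_proportion_test(a$tn, a$tn + a$fp, b$tn, b$tn + b$fp)
  }
  pv <- list(sens_vd = cmp("sensitivity", dd, vd),
             spec_vd = cmp("specificity", dd, vd))
  if (!is.null(rvd)) {
    rvd <- as.list(rvd)
    pv$sens_rvd <- cmp("sensitivity", dd, rvd)
    pv$spec_rvd <- cmp("specificity", dd, rvd)
  }
  sens_ok <- pv$sens_vd >= alpha || (!is.null(pv$sens_rvd) && pv$sens_rvd >= alpha)
  spec_ok <- pv$spec_vd >= alpha || (!is.null(pv$spec_rvd) && pv$spec_rvd >= alpha)
  overall <- if (sens_ok && spec_ok) "both"
             else if (sens_ok) "sensitivity_only"
             else if (spec_ok) "specificity_only"
             else "neither"
  list(sensitivity = sens_ok, specificity = spec_ok, p_values = pv,
       overall = overall)
}
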