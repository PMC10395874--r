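#' Derive a clinical decision rule for an FN outcome
#'
#' The central fitting function: runs the full derivation procedure on an
#' episode table for one outcome — univariable screen, stepwise forward
#' selection with the cross-validated overfitting guard, final mixed
#' logistic fit, integer weight derivation, and sensitivity-targeted
#' threshold calibration — and returns a classed model object with the
#' usual methods (`print`, `summary`, `coef`, `predict`, `plot`).
#'
#' @param data episode data frame (see [fn_episode_schema()]).
#' @param outcome `"bacteremia"`, `"smc"` or `"sre"`.
#' @param candidates characteristics entering the univariable screen.
#' @param alpha_screen univariable significance level.
#' @param alpha_entry forward-selection entry level.
#' @param guard_reps,guard_folds overfitting-guard cross-validation size.
#' @param min_sensitivity threshold calibration target (default 0.90).
#' @param cv_reps replications of the final internal cross-validation
#'   (0 skips it).
#' @param cv_folds folds of the final internal cross-validation.
#' @param cv_engine per-fold refit engine for the final CV (see
#'   [internal_cv()]).
#' @param seed integer seed (guard and CV fold draws).
#' @param grouping random-intercept structure of the mixed fits.
#' @return object of class `fn_cdr`.
#' @export
derive_cdr <- function(data, outcome,
                       candidates = fn_characteristics(),
                       alpha_screen = 0.05, alpha_entry = 0.05,
                       guard_reps = 100L, guard_folds = 10L,
                       min_sensitivity = 0.90,
                       cv_reps = 0L, cv_folds = 10L,
                       cv_engine = c("mixed", "glm"),
                       seed = 1L,
                       grouping = c("center_patient", "patient", "none")) {
  grouping <- match.arg(grouping)
  cv_engine <- match.arg(cv_engine)
  validate_episodes(data)
  if (length(unique(data[[outcome]])) < 2)
    stop("input error: outcome '", outcome, "' has a single class",
         call. = FALSE)
  screen <- univariable_screen(data, outcome, candidates, alpha_screen,
                               grouping)
  # only score-compatible forms (binary / categorical) can carry integer
  # weights; continuous blood counts stay in the screen for reporting but
  # their thresholded forms are the ones a points score can use
  scoreable <- Filter(function(ch) term_info(ch)$type != "continuous",
                      screen$significant)
  sel <- forward_select(data, outcome, scoreable, alpha_entry,
                        guard_reps, guard_folds, seed, grouping)
  if (!length(sel$selected))
    stop("derivation error: no characteristic entered the model for '",
         outcome, "'", call. = FALSE)
  fit <- fit_mixed_logit(data, outcome, sel$selected, grouping)
  score <- derive_weights(fit)
  scores <- apply_score(score, data)
  thr <- calibrate_threshold(scores, data[[outcome]], min_sensitivity)
  score$threshold <- as.integer(thr)
  perf_tab <- threshold_performance_table(scores, data[[outcome]])
  perf <- performance(confusion_matrix(scores >= thr, data[[outcome]]),
                      auroc = auroc(scores, data[[outcome]]))
  cv <- NULL
  if (cv_reps > 0)
    cv <- internal_cv(data, outcome, sel$selected, cv_reps, cv_folds,
                      min_sensitivity, seed = substream(seed, 77L),
                      engine = cv_engine, grouping = grouping)
  structure(list(outcome = outcome, screen = screen, selection = sel,
                 fit = fit, score = score, threshold = as.integer(thr),
                 threshold_sensitivity = attr(thr, "sensitivity"),
                 performance_table = perf_tab, performance = perf,
                 cv = cv, min_sensitivity = min_sensitivity, seed = seed,
                 n = nrow(data)),
            class = "fn_cdr")
}

#' Per-threshold performance table
#'
#' Confusion counts and performance (with CIs, in percent) of `score >= T`
#' for every integer threshold between the minimum and maximum observed
#' score plus one.
#'
#' @param scores integer scores.
#' @param y binary outcome.
#' @return data frame, one row per threshold.
#' @export
threshold_performance_table <- function(scores, y) {
  rows <- lapply(seq(min(scores), max(scores) + 1L), function(t) {
    cm <- confusion_matrix(scores >= t, y)
    p <- performance(cm)
    m <- p$metrics
    out <- data.frame(threshold = t, tp = cm$tp, tn = cm$tn, fp = cm$fp,
                      fn = cm$fn, low_risk = p$low_risk)
    for (i in seq_len(nrow(m))) {
      out[[m$metric[i]]] <- m$estimate[i]
      out[[paste0(m$metric[i], "_lower")]] <- m$lower[i]
      out[[paste0(m$metric[i], "_upper")]] <- m$upper[i]
    }
    out
  })
  do.call(rbind, rows)
}

#' @export
print.fn_cdr <- function(x, ...) {
  cat(sprintf("FN clinical decision rule for %s (n = %d episodes)\n",
              x$outcome, x$n))
  cat("Selected characteristics:",
      paste(x$selection$selected, collapse = ", "), "\n")
  print(x$score)
  m <- x$performance$metrics
  cat(sprintf("At threshold >= %d: sensitivity %.1f%%, specificity %.1f%%, AUROC %.3f\n",
              x$threshold, m$estimate[m$metric == "sensitivity"],
              m$estimate[m$metric == "specificity"], x$performance$auroc))
  invisible(x)
}

#' @export
summary.fn_cdr <- function(object, ...) {
  print(object)
  cat("\nFinal mixed model:\n")
  print(object$fit)
  cat("\nSelection log:\n")
  print(object$selection$step_log)
  if (!is.null(object$cv)) {
    cat("\n")
    print(object$cv)
  }
  invisible(object)
}

#' @export
coef.fn_cdr <- function(object, ...) object$fit$coefficients

#' Score or classify new episodes with a derived CDR
#'
#' @param object `fn_cdr`.
#' @param newdata episode data frame.
#' @param type `"score"` (integer points), `"class"` (`"high"`/`"low"`), or
#'   `"link"` (fixed-effects linear predictor of the underlying model).
#' @param ... unused.
#' @export
predict.fn_cdr <- function(object, newdata,
                           type = c("score", "class", "link"), ...) {
  type <- match.arg(type)
  if (type == "link") return(predict(object$fit, newdata))
  s <- apply_score(object$score, newdata)
  if (type == "score") return(s)
  factor(ifelse(s >= object$threshold, "high", "low"),
         levels = c("low", "high"))
}

#' ROC curve of a derived CDR
#'
#' Empirical ROC of the integer score on the derivation data, with the
#' calibrated threshold marked.
#'
#' @param x `fn_cdr`.
#' @param ... passed to `plot()`.
#' @export
plot.fn_cdr <- function(x, ...) {
  tab <- x$performance_table
  fpr <- c(100, 100 - tab$specificity, 0) / 100
  tpr <- c(100, tab$sensitivity, 0) / 100
  ord <- order(fpr, tpr)
  graphics::plot(fpr[ord], tpr[ord], type = "b", pch = 16,
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("CDR for %s (AUROC %.3f)", x$outcome,
                                x$performance$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  i <- which(tab$threshold == x$threshold)
  graphics::points((100 - tab$specificity[i]) / 100, tab$sensitivity[i] / 100,
                   col = 2, cex = 2)
  graphics::text((100 - tab$specificity[i]) / 100, tab$sensitivity[i] / 100,
                 labels = sprintf(">= %d", x$threshold), pos = 4, col = 2)
  invisible(x)
}
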