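# Integer points score machinery: weight derivation from logistic
# coefficients, score application, sensitivity-targeted threshold
# calibration, forward selection with an overfitting guard, and replicated
# internal cross-validation with in-fold re-derivation.

#' Derive integer score weights from logistic coefficients
#'
#' Each characteristic's weight is its log-odds coefficient multiplied by two
#' (to increase discrimination between coefficients) and rounded to the
#' nearest integer, half away from zero. The reference level of a categorical
#' characteristic starts at 0. Negative weights are avoided per
#' characteristic block: if any weight in a block is negative, the lowest
#' weight's absolute value is added to every weight of that block (reference
#' included). The maximum score is the sum over characteristics of their
#' largest weight.
#'
#' @param fit an `fn_fit`, or a coefficient specification: a named list
#'   mapping each characteristic to a scalar coefficient (binary) or a named
#'   vector over its levels (categorical; reference at 0).
#' @param outcome outcome label stored in the score (taken from the fit when
#'   available).
#' @return object of class `fn_score` with per-level integer weights,
#'   per-block offsets, `max_score`, an unset threshold, and the coefficients
#'   used as provenance.
#' @export
derive_weights <- function(fit, outcome = NULL) UseMethod("derive_weights")

#' @export
derive_weights.fn_fit <- function(fit, outcome = NULL) {
  if (any(!is.finite(fit$coefficients)))
    stop("derivation error: non-finite coefficients", call. = FALSE)
  spec <- list()
  for (t in fit$terms) {
    info <- term_info(t)
    if (info$type == "categorical") {
      lev <- fit$xlevels[[t]]
      co <- stats::setNames(numeric(length(lev)), lev)
      for (l in lev[-1]) co[l] <- fit$coefficients[[paste0(t, l)]]
      spec[[t]] <- co
    } else if (info$type == "continuous") {
      stop("derivation error: continuous characteristic '", t,
           "' cannot carry an integer score weight; dichotomize it first",
           call. = FALSE)
    } else {
      spec[[t]] <- fit$coefficients[[t]]
    }
  }
  derive_weights.default(spec, outcome %||% fit$outcome)
}

#' @export
derive_weights.default <- function(fit, outcome = NULL) {
  spec <- fit
  if (!length(spec)) stop("derivation error: empty coefficient set",
                          call. = FALSE)
  if (any(!is.finite(unlist(spec))))
    stop("derivation error: non-finite coefficient", call. = FALSE)
  weights <- list()
  offsets <- integer(0)
  for (ch in names(spec)) {
    co <- spec[[ch]]
    if (length(co) > 1) {
      raw <- round_half_away(2 * co)
    } else {
      raw <- c(`0` = 0L, `1` = round_half_away(2 * co))
    }
    off <- max(0L, -min(raw))
    weights[[ch]] <- raw + off
    offsets[ch] <- off
  }
  structure(list(
    outcome = outcome,
    weights = weights,
    offsets = offsets,
    threshold = NA_integer_,
    max_score = sum(vapply(weights, max, integer(1))),
    provenance = spec
  ), class = "fn_score")
}

#' @export
print.fn_score <- function(x, ...) {
  cat(sprintf("Integer risk score%s: max %d points, threshold %s\n",
              if (is.null(x$outcome)) "" else paste0(" for ", x$outcome),
              x$max_score,
              if (is.na(x$threshold)) "unset" else paste0(">= ", x$threshold)))
  for (ch in names(x$weights)) {
    w <- x$weights[[ch]]
    if (identical(names(w), c("0", "1")))
      cat(sprintf("  %s: %d point(s)%s\n", ch, w[["1"]],
                  if (x$offsets[[ch]] > 0)
                    sprintf(" (absent: %d; block offset +%d)", w[["0"]],
                            x$offsets[[ch]]) else ""))
    else
      cat(sprintf("  %s: %s%s\n", ch,
                  paste(names(w), w, sep = "=", collapse = ", "),
                  if (x$offsets[[ch]] > 0)
                    sprintf(" (block offset +%d)", x$offsets[[ch]]) else ""))
  }
  invisible(x)
}

#' Apply an integer score to episodes
#'
#' Sums the applicable weight of every characteristic in the score.
#'
#' @param score `fn_score`.
#' @param data episode data frame providing every score characteristic.
#' @return integer vector of scores in `[0, max_score]`.
#' @export
apply_score <- function(score, data) {
  total <- integer(nrow(data))
  for (ch in names(score$weights)) {
    w <- score$weights[[ch]]
    v <- term_value(data, ch)
    key <- as.character(v)
    if (any(!key %in% names(w)))
      stop("input error: characteristic '", ch, "' has value(s) outside the ",
           "score's levels", call. = FALSE)
    total <- total + unname(w[key])
  }
  total
}

#' Calibrate the score threshold to a target sensitivity
#'
#' Returns the largest integer threshold `T` such that classifying
#' `score >= T` as high risk reaches the target sensitivity (>= 90% by
#' default). When several thresholds reach it, the largest (most specific)
#' is taken. The minimum observed score (everyone high risk, sensitivity 1)
#' always qualifies, so a threshold always exists; the result carries the
#' achieved sensitivity as attribute `sensitivity` and `all_high = TRUE`
#' when only the degenerate all-high-risk threshold qualified.
#'
#' @param scores integer scores.
#' @param flags binary outcome per episode.
#' @param min_sensitivity target sensitivity in (0, 1].
#' @return integer threshold with attributes `sensitivity` and `all_high`.
#' @export
calibrate_threshold <- function(scores, flags, min_sensitivity = 0.90) {
  if (sum(flags) < 1)
    stop("precondition error: no positive outcomes to calibrate against",
         call. = FALSE)
  cand <- seq(min(scores), max(scores) + 1L)
  sens <- vapply(cand, function(t) mean(scores[flags == 1] >= t), numeric(1))
  ok <- which(sens >= min_sensitivity)
  t_star <- cand[max(ok)]
  structure(as.integer(t_star),
            sensitivity = sens[max(ok)],
            all_high = length(ok) == 1 && t_star == min(scores))
}

#' Select the threshold from per-threshold sensitivities
#'
#' Variant of [calibrate_threshold()] operating on a published
#' threshold-by-threshold performance table rather than raw scores: returns
#' the largest listed threshold whose sensitivity reaches the target.
#'
#' @param thresholds integer candidate thresholds.
#' @param sensitivities sensitivities on the same scale as
#'   `min_sensitivity` (proportions in `[0, 1]` or percentages).
#' @param min_sensitivity target (default 0.90; use 90 with percentages).
#' @return the selected integer threshold.
#' @export
threshold_from_sensitivities <- function(thresholds, sensitivities,
                                         min_sensitivity = 0.90) {
  stopifnot(length(thresholds) == length(sensitivities))
  ok <- sensitivities >= min_sensitivity
  if (!any(ok))
    stop("no listed threshold reaches the target sensitivity", call. = FALSE)
  as.integer(max(thresholds[ok]))
}

# Out-of-fold fixed-effects linear predictor AUROC, repeated; used as the
# overfitting guard during forward selection. Per-fold refits are plain
# logistic regressions (held-out episodes are scored with fixed effects
# only).
cv_median_auroc <- function(data, outcome, terms, reps, folds, seed,
                            fold_by = "episode") {
  mf <- build_model_frame(data, outcome, terms)
  y <- mf$.y
  set.seed(seed)
  aucs <- numeric(reps)
  for (r in seq_len(reps)) {
    fid <- make_folds(y, folds, fold_by, patient_id = data$patient_id)
    lp <- numeric(length(y))
    for (k in seq_len(folds)) {
      test <- fid == k
      m <- suppressWarnings(
        stats::glm(fit_formula(terms, "none"),
                   data = mf[!test, , drop = FALSE],
                   family = stats::binomial()))
      lp[test] <- stats::predict(m, newdata = mf[test, , drop = FALSE])
    }
    aucs[r] <- auroc(lp, y)
  }
  stats::median(aucs)
}

#' Stepwise forward selection with a cross-validated overfitting guard
#'
#' At each step the candidate with the smallest entry p-value below
#' `alpha_entry` is added (Wald test for single-coefficient characteristics,
#' joint likelihood-ratio test for categorical blocks, fitted by the mixed
#' model of [fit_mixed_logit()]). After each addition, the median AUROC of
#' the model's fixed-effect linear predictor over `guard_reps` replications
#' of `guard_folds`-fold cross-validation is computed; if it decreased
#' versus the previous step, the addition is rolled back (overfitting) and
#' selection stops.
#'
#' @param data episode data frame.
#' @param outcome outcome name.
#' @param candidates candidate characteristics (normally the
#'   univariable-significant set).
#' @param alpha_entry entry significance level (default 0.05).
#' @param guard_reps,guard_folds replications and folds of the guard CV.
#' @param seed integer seed for the guard CV fold draws.
#' @param grouping random-intercept structure for the entry fits.
#' @return list with `selected` (character vector, possibly empty) and
#'   `step_log` (data frame: step, characteristic, p_entry,
#'   median_cv_auroc, action).
#' @export
forward_select <- function(data, outcome, candidates, alpha_entry = 0.05,
                           guard_reps = 100L, guard_folds = 10L, seed = 1L,
                           grouping = c("center_patient", "patient", "none")) {
  grouping <- match.arg(grouping)
  selected <- character(0)
  remaining <- candidates
  log_rows <- list()
  prev_auc <- -Inf
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    ps <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      out <- tryCatch(
        entry_p_value(data, outcome, selected, remaining[i], grouping),
        error = identity)
      if (inherits(out, "condition") || isTRUE(out$fit$separation)) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          step = step, characteristic = remaining[i], p_entry = NA_real_,
          median_cv_auroc = NA_real_, action = "skipped_fit_failure",
          stringsAsFactors = FALSE)
        next
      }
      ps[i] <- out$p
    }
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= alpha_entry) break
    best <- remaining[which.min(ps)]
    p_best <- min(ps, na.rm = TRUE)
    med_auc <- cv_median_auroc(data, outcome, c(selected, best),
                               guard_reps, guard_folds,
                               seed = substream(seed, step))
    if (med_auc < prev_auc) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        step = step, characteristic = best, p_entry = p_best,
        median_cv_auroc = med_auc, action = "rolled_back_overfit",
        stringsAsFactors = FALSE)
      break
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = step, characteristic = best, p_entry = p_best,
      median_cv_auroc = med_auc, action = "entered", stringsAsFactors = FALSE)
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    prev_auc <- med_auc
  }
  list(selected = selected,
       step_log = if (length(log_rows)) do.call(rbind, log_rows)
                  else data.frame(step = integer(), characteristic = character(),
                                  p_entry = numeric(), median_cv_auroc = numeric(),
                                  action = character(), stringsAsFactors = FALSE))
}

#' Replicated k-fold internal cross-validation of a CDR
#'
#' For each replication, episodes are partitioned into outcome-stratified
#' folds; for each fold the model is refitted on the training folds, the
#' integer score re-derived, the threshold re-calibrated on the training
#' folds, and the held-out episodes classified (fixed effects only).
#' Per-replication performance is pooled over folds; the summary reports the
#' median and 2.5/97.5 percentiles of sensitivity, specificity, PPV and NPV
#' across replications. A fold whose refit fails is downgraded via the
#' fallback ladder (or to plain logistic regression with `engine = "glm"`);
#' a replication with a persistent failure is dropped and counted.
#'
#' @param data episode data frame.
#' @param outcome outcome name.
#' @param terms the selected characteristics of the CDR.
#' @param reps number of cross-validation replications.
#' @param folds folds per replication.
#' @param min_sensitivity threshold calibration target.
#' @param seed integer seed.
#' @param engine `"mixed"` refits the mixed model per fold; `"glm"` refits
#'   plain logistic regressions (much faster; held-out episodes are scored
#'   with fixed effects only in both cases).
#' @param grouping random-intercept structure for `engine = "mixed"`.
#' @param fold_by `"episode"` (outcome-stratified, default) or `"patient"`
#'   (whole patients per fold).
#' @return object of class `fn_cv`: `summary` (metric, median, lower,
#'   upper, in percent), `raw` (replication-by-metric matrix), `reps`,
#'   `folds`, `dropped`, `seed`.
#' @export
internal_cv <- function(data, outcome, terms, reps = 1000L, folds = 10L,
                        min_sensitivity = 0.90, seed = 1L,
                        engine = c("mixed", "glm"),
                        grouping = c("center_patient", "patient", "none"),
                        fold_by = c("episode", "patient")) {
  engine <- match.arg(engine)
  grouping <- match.arg(grouping)
  fold_by <- match.arg(fold_by)
  y <- data[[outcome]]
  raw <- matrix(NA_real_, reps, 4,
                dimnames = list(NULL, c("sensitivity", "specificity",
                                        "ppv", "npv")))
  dropped <- 0L
  for (r in seq_len(reps)) {
    set.seed(substream(seed, 1000L + r))
    fid <- make_folds(y, folds, fold_by, patient_id = data$patient_id)
    high <- rep(NA, length(y))
    failed <- FALSE
    for (k in seq_len(folds)) {
      test <- fid == k
      train <- data[!test, , drop = FALSE]
      if (length(unique(train[[outcome]])) < 2) { failed <- TRUE; break }
      fit <- tryCatch({
        if (engine == "mixed")
          fit_mixed_logit(train, outcome, terms, grouping)
        else
          fit_mixed_logit(train, outcome, terms, "none")
      }, error = identity)
      if (inherits(fit, "condition")) { failed <- TRUE; break }
      sc <- tryCatch(derive_weights(fit), error = identity)
      if (inherits(sc, "condition")) { failed <- TRUE; break }
      thr <- calibrate_threshold(apply_score(sc, train), train[[outcome]],
                                 min_sensitivity)
      high[test] <- apply_score(sc, data[test, , drop = FALSE]) >= thr
    }
    if (failed) { dropped <- dropped + 1L; next }
    tp <- sum(high & y == 1); fn_ <- sum(!high & y == 1)
    tn <- sum(!high & y == 0); fp <- sum(high & y == 0)
    raw[r, ] <- c(tp / (tp + fn_), tn / (tn + fp),
                  if (tp + fp > 0) tp / (tp + fp) else NA,
                  if (tn + fn_ > 0) tn / (tn + fn_) else NA) * 100
  }
  ok <- stats::complete.cases(raw[, 1:2, drop = FALSE])
  summ <- data.frame(
    metric = colnames(raw),
    median = apply(raw, 2, stats::median, na.rm = TRUE),
    lower = apply(raw, 2, stats::quantile, probs = 0.025, na.rm = TRUE),
    upper = apply(raw, 2, stats::quantile, probs = 0.975, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(summary = summ, raw = raw, reps = reps, folds = folds,
                 dropped = dropped, seed = seed, outcome = outcome,
                 terms = terms),
            class = "fn_cv")
}

#' @export
print.fn_cv <- function(x, ...) {
  cat(sprintf("Internal cross-validation: %d x %d-fold (%d dropped), outcome %s\n",
              x$reps, x$folds, x$dropped, x$outcome))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s median %5.1f%% (95%% CI %5.1f-%5.1f)\n",
                s$metric[i], s$median[i], s$lower[i], s$upper[i]))
  invisible(x)
}
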