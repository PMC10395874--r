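# Three-level mixed logistic regression (random intercepts per patient
# nested within centers) with a graceful fallback ladder, plus the
# univariable and interaction screens.

grouping_levels <- c(center_patient = 3L, patient = 2L, none = 1L)

fit_formula <- function(terms, grouping) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  re <- switch(grouping,
               center_patient = " + (1 | .center) + (1 | .patient)",
               patient = " + (1 | .patient)",
               none = "")
  stats::as.formula(paste0(".y ~ ", rhs, re))
}

# One fit at a fixed level of the ladder; returns the model object or an
# error condition.
fit_one <- function(mf, terms, grouping) {
  form <- fit_formula(terms, grouping)
  if (grouping == "none")
    return(tryCatch(
      suppressWarnings(stats::glm(form, data = mf,
                                  family = stats::binomial())),
      error = identity))
  tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(form, data = mf, family = stats::binomial(), nAGQ = 1L,
                  control = lme4::glmerControl(optimizer = "bobyqa"))
    )),
    error = identity
  )
}

# "Model failure" of a mixed fit, operationalized as optimizer
# non-convergence, a non-finite likelihood, a singular Hessian, or a scaled
# gradient (Hessian-solved, as in lme4's convergence check) above 1e-3 at
# the returned point.
mixed_fit_failed <- function(m, grad_tol = 1e-3) {
  if (inherits(m, "condition")) return(TRUE)
  ll <- as.numeric(stats::logLik(m))
  if (!is.finite(ll)) return(TRUE)
  if (!is.null(m@optinfo$conv$opt) && m@optinfo$conv$opt != 0) return(TRUE)
  dv <- m@optinfo$derivs
  if (!is.null(dv)) {
    if (any(!is.finite(dv$gradient)) || any(!is.finite(dv$Hessian)))
      return(TRUE)
    sg <- tryCatch(solve(dv$Hessian, dv$gradient), error = identity)
    if (inherits(sg, "condition")) return(TRUE)
    if (max(abs(sg)) > grad_tol) return(TRUE)
  }
  FALSE
}

#' Fit a mixed logistic regression with a fallback ladder
#'
#' Fits the outcome on the requested characteristics by Laplace-approximated
#' (nAGQ = 1) mixed logistic regression with random intercepts per patient
#' nested within centers. If the three-level optimization fails
#' (non-convergence, non-finite likelihood, or gradient norm above 1e-3),
#' the model is refitted with a patient-only random intercept, and failing
#' that as a plain logistic regression; `levels_used` records the level
#' reached. The fit is deterministic given the data (no randomness in
#' optimization).
#'
#' @param data episode data frame.
#' @param outcome `"bacteremia"`, `"smc"` or `"sre"`.
#' @param terms character vector of characteristic names (may be empty for
#'   an intercept-only model); categorical characteristics expand to
#'   reference-coded indicators (ALL is the malignancy reference).
#' @param grouping requested random-intercept structure:
#'   `"center_patient"` (three-level), `"patient"`, or `"none"`.
#' @param allow_fallback drop down the ladder on model failure (otherwise a
#'   failed fit is an error).
#' @return object of class `fn_fit`: coefficients, standard errors, odds
#'   ratios with 95% CI, two-tailed Wald p-values, random-intercept SDs
#'   `sigma_center` / `sigma_patient`, the maximized marginal log-likelihood,
#'   `levels_used` (3, 2 or 1) and a separation flag.
#' @export
fit_mixed_logit <- function(data, outcome, terms = character(),
                            grouping = c("center_patient", "patient", "none"),
                            allow_fallback = TRUE) {
  grouping <- match.arg(grouping)
  mf <- build_model_frame(data, outcome, terms)
  if (length(unique(mf$.y)) < 2)
    stop("input error: outcome '", outcome, "' has a single class",
         call. = FALSE)
  ladder <- switch(grouping,
                   center_patient = c("center_patient", "patient", "none"),
                   patient = c("patient", "none"),
                   none = "none")
  if (!allow_fallback) ladder <- ladder[1]
  m <- NULL
  used <- NULL
  for (g in ladder) {
    cand <- fit_one(mf, terms, g)
    ok <- if (g == "none") !inherits(cand, "condition")
          else !mixed_fit_failed(cand)
    if (ok) { m <- cand; used <- g; break }
  }
  if (is.null(m))
    stop("model failure: no level of the fallback ladder converged for outcome '",
         outcome, "'", call. = FALSE)
  new_fn_fit(m, mf, outcome, terms, used)
}

new_fn_fit <- function(m, mf, outcome, terms, grouping) {
  mixed <- inherits(m, "merMod")
  beta <- if (mixed) lme4::fixef(m) else stats::coef(m)
  V <- as.matrix(stats::vcov(m))
  se <- sqrt(diag(V))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  sig_c <- 0
  sig_p <- 0
  if (mixed) {
    vc <- lme4::VarCorr(m)
    if (!is.null(vc$.center)) sig_c <- sqrt(vc$.center[1, 1])
    if (!is.null(vc$.patient)) sig_p <- sqrt(vc$.patient[1, 1])
  }
  xlev <- list()
  for (t in terms) {
    info <- term_info(t)
    if (info$type == "categorical")
      xlev[[t]] <- levels(mf[[t]])
  }
  structure(list(
    outcome = outcome,
    terms = terms,
    coefficients = beta,
    se = se,
    or = exp(beta),
    or_ci = cbind(lower = exp(beta - 1.959964 * se),
                  upper = exp(beta + 1.959964 * se)),
    p_values = p,
    sigma_center = sig_c,
    sigma_patient = sig_p,
    logLik = as.numeric(stats::logLik(m)),
    levels_used = unname(grouping_levels[grouping]),
    grouping = grouping,
    separation = any(!is.finite(se)) || any(abs(beta) > 15) || any(se > 100),
    xlevels = xlev,
    model = m
  ), class = "fn_fit")
}

#' @export
print.fn_fit <- function(x, ...) {
  cat(sprintf("Mixed logistic fit: outcome %s, %d-level, logLik %.2f\n",
              x$outcome, x$levels_used, x$logLik))
  tab <- data.frame(coef = round(x$coefficients, 3),
                    se = round(x$se, 3),
                    OR = round(x$or, 2),
                    ci_low = round(x$or_ci[, "lower"], 2),
                    ci_high = round(x$or_ci[, "upper"], 2),
                    p = signif(x$p_values, 2))
  print(tab)
  cat(sprintf("sigma_center = %.3f, sigma_patient = %.3f\n",
              x$sigma_center, x$sigma_patient))
  if (x$separation)
    cat("WARNING: separation suspected (unstable coefficients)\n")
  invisible(x)
}

#' @export
coef.fn_fit <- function(object, ...) object$coefficients

#' @export
logLik.fn_fit <- function(object, ...) {
  structure(object$logLik, class = "logLik",
            df = length(object$coefficients) +
              (object$levels_used >= 2) + (object$levels_used >= 3))
}

#' Fixed-effects linear predictor
#'
#' Evaluates intercept + sum(coefficient x covariate) on new episodes, with
#' all random effects set to zero.
#'
#' @param object `fn_fit`.
#' @param newdata episode data frame providing every model characteristic.
#' @param ... unused.
#' @return numeric vector (log-odds scale).
#' @export
predict.fn_fit <- function(object, newdata, ...) {
  mf <- data.frame(row.names = seq_len(nrow(newdata)))
  for (t in object$terms) mf[[t]] <- term_value(newdata, t)
  rhs <- if (length(object$terms)) paste(object$terms, collapse = " + ") else "1"
  X <- stats::model.matrix(stats::as.formula(paste0("~ ", rhs)), mf,
                           xlev = object$xlevels)
  unname(drop(X[, names(object$coefficients), drop = FALSE] %*%
                object$coefficients))
}

# Likelihood-ratio test of `terms_full` vs `terms_reduced`, both refitted at
# the same ladder level as `fit` (fallback disabled for comparability).
lrt_terms <- function(data, outcome, terms_full, terms_reduced, grouping) {
  f1 <- fit_mixed_logit(data, outcome, terms_full, grouping,
                        allow_fallback = FALSE)
  f0 <- fit_mixed_logit(data, outcome, terms_reduced, grouping,
                        allow_fallback = FALSE)
  df <- length(f1$coefficients) - length(f0$coefficients)
  stat <- max(0, 2 * (f1$logLik - f0$logLik))
  list(p = stats::pchisq(stat, df, lower.tail = FALSE), stat = stat, df = df,
       fit = f1)
}

# Entry p-value of one characteristic added to a base model: Wald for a
# single-coefficient term, joint LRT for a categorical block.
entry_p_value <- function(data, outcome, base_terms, characteristic, grouping) {
  full <- fit_mixed_logit(data, outcome, c(base_terms, characteristic),
                          grouping)
  info <- term_info(characteristic)
  if (info$type == "categorical") {
    lr <- lrt_terms(data, outcome, c(base_terms, characteristic), base_terms,
                    full$grouping)
    list(p = lr$p, fit = full)
  } else {
    idx <- grep(paste0("^", characteristic, "$"), names(full$coefficients))
    list(p = unname(full$p_values[idx]), fit = full)
  }
}

#' Univariable association screen
#'
#' Fits one mixed logistic model per characteristic and returns the set
#' significantly associated with the outcome: Wald two-tailed p-value for
#' binary and continuous characteristics, joint likelihood-ratio test for
#' categorical ones. Failed fits are reported as not evaluable; they do not
#' abort the screen.
#'
#' @param data episode data frame.
#' @param outcome outcome name.
#' @param characteristics candidate characteristics (default all 20).
#' @param alpha significance level for selection (default 0.05).
#' @param grouping random-intercept structure, as in [fit_mixed_logit()].
#' @return list with `results` (data frame: characteristic, p_value,
#'   evaluable, levels_used, ordered by p), `significant` (character vector),
#'   and `fits` (per-characteristic `fn_fit`s).
#' @export
univariable_screen <- function(data, outcome,
                               characteristics = fn_characteristics(),
                               alpha = 0.05,
                               grouping = c("center_patient", "patient", "none")) {
  grouping <- match.arg(grouping)
  res <- data.frame(characteristic = characteristics,
                    p_value = NA_real_, evaluable = FALSE,
                    levels_used = NA_integer_, stringsAsFactors = FALSE)
  fits <- list()
  for (i in seq_along(characteristics)) {
    ch <- characteristics[i]
    out <- tryCatch(entry_p_value(data, outcome, character(), ch, grouping),
                    error = identity)
    if (inherits(out, "condition")) next
    if (out$fit$separation) next
    res$p_value[i] <- out$p
    res$evaluable[i] <- TRUE
    res$levels_used[i] <- out$fit$levels_used
    fits[[ch]] <- out$fit
  }
  res <- res[order(res$p_value), ]
  sig <- res$characteristic[res$evaluable & !is.na(res$p_value) &
                              res$p_value < alpha]
  list(results = res, significant = sig, fits = fits, alpha = alpha)
}

#' Interaction screen against the randomized fever limit
#'
#' Tests whether a characteristic's association with the outcome differs
#' between the two randomized fever limits (38.5 vs 39.0 degrees C): the
#' model with main effects plus the characteristic-by-limit interaction is
#' compared to the main-effects model by likelihood-ratio test. The default
#' alpha of 0.01 accounts for the large number of interaction analyses.
#'
#' @inheritParams univariable_screen
#' @param characteristic single characteristic name.
#' @param alpha significance level (default 0.01).
#' @return list with `p_value`, `significant`, `levels_used`.
#' @export
interaction_screen <- function(data, outcome, characteristic, alpha = 0.01,
                               grouping = c("center_patient", "patient", "none")) {
  grouping <- match.arg(grouping)
  if (length(unique(data$randomized_fever_limit)) < 2)
    stop("precondition error: randomized_fever_limit has a single level",
         call. = FALSE)
  mf <- build_model_frame(data, outcome, characteristic)
  mf$.limit <- as.integer(data$randomized_fever_limit == 39.0)
  if (length(unique(mf$.y)) < 2)
    stop("input error: outcome '", outcome, "' has a single class",
         call. = FALSE)
  fit_ix <- function(with_interaction, g, fallback = TRUE) {
    terms <- if (with_interaction)
      c(characteristic, ".limit", paste0(characteristic, ":.limit"))
    else c(characteristic, ".limit")
    ladder <- switch(g, center_patient = c("center_patient", "patient", "none"),
                     patient = c("patient", "none"), none = "none")
    if (!fallback) ladder <- ladder[1]
    for (gl in ladder) {
      cand <- fit_one(mf, terms, gl)
      ok <- if (gl == "none") !inherits(cand, "condition")
            else !mixed_fit_failed(cand)
      if (ok) return(list(m = cand, g = gl))
    }
    stop("model failure in interaction screen for '", characteristic, "'",
         call. = FALSE)
  }
  full <- fit_ix(TRUE, grouping)
  red <- fit_ix(FALSE, full$g, fallback = FALSE)
  df <- length(stats::coef(summary(full$m))[, 1]) -
    length(stats::coef(summary(red$m))[, 1])
  stat <- max(0, 2 * (as.numeric(stats::logLik(full$m)) -
                        as.numeric(stats::logLik(red$m))))
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(p_value = p, significant = p < alpha,
       levels_used = unname(grouping_levels[full$g]))
}
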