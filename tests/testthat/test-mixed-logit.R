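test_that("zero-variance data: mixed fit matches the plain-logistic oracle", {
  # generative model restricted to the two fitted terms, so there is no
  # omitted patient-level heterogeneity for the random intercept to absorb
  spec <- list(bacteremia = list(severely_reduced_general_condition = 1.56,
                                 leucocyte_lt_0_3 = 1.69),
               smc = list(sex = 0))
  cfg <- cohort_config(n_patients = 2200L, sigma_center = 0,
                       sigma_patient = 0, outcome_coefficients = spec,
                       seed = 71L)
  d <- generate_cohort(cfg)
  terms <- c("severely_reduced_general_condition", "leucocyte_lt_0_3")
  fit <- fit_mixed_logit(d, "bacteremia", terms)
  expect_lt(fit$sigma_center, 0.1)
  expect_lt(fit$sigma_patient, 0.1)

  # independent oracle: IRLS logistic fit on a hand-built design matrix
  X <- cbind(1, d$severely_reduced_general_condition,
             as.integer(d$leucocyte_count < 0.3))
  oracle <- glm.fit(X, d$bacteremia, family = binomial())
  se <- sqrt(diag(chol2inv(chol(t(X * oracle$weights) %*% X))))
  expect_true(all(abs(fit$coefficients - oracle$coefficients) < 2 * se))

  # at the variance boundary the fits should agree essentially exactly
  if (fit$sigma_center < 1e-6 && fit$sigma_patient < 1e-6)
    expect_lt(max(abs(fit$coefficients - oracle$coefficients)), 1e-4)
})

test_that("intercept-only fit on a balanced outcome returns intercept zero", {
  d <- episode_stub(40, bacteremia = rep(c(0L, 1L), 20))
  fit <- fit_mixed_logit(d, "bacteremia", grouping = "none")
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), 0, tolerance = 1e-8)
})

test_that("single-class outcomes are rejected", {
  d <- episode_stub(10, bacteremia = 0L)
  expect_error(fit_mixed_logit(d, "bacteremia"), "single class")
})

test_that("fixed-effects linear predictor is intercept plus coefficient sums", {
  fit <- structure(list(
    outcome = "bacteremia",
    terms = "severely_reduced_general_condition",
    coefficients = c(`(Intercept)` = -2,
                     severely_reduced_general_condition = 1.56),
    xlevels = list()), class = "fn_fit")
  expect_equal(predict(fit, episode_stub(1, severely_reduced_general_condition = 1L)),
               -0.44)
  expect_equal(predict(fit, episode_stub(1)), -2)
  fit$coefficients["severely_reduced_general_condition"] <- 0
  d <- episode_stub(5, severely_reduced_general_condition = c(0L, 1L, 0L, 1L, 1L))
  expect_equal(unname(predict(fit, d)), rep(-2, 5))
  expect_error(predict(fit, d[, setdiff(names(d), "severely_reduced_general_condition")]),
               "severely_reduced_general_condition")
})

test_that("Laplace objective agrees with direct numerical integration on a small-sigma toy", {
  set.seed(12)
  y <- rbinom(20, 1, 0.55)
  g <- factor(rep(1:2, each = 10))
  mf <- data.frame(.y = y, .patient = g)
  dd <- suppressWarnings(
    lme4::glmer(fncdr:::fit_formula(character(), "patient"), data = mf,
                family = binomial(), devFunOnly = TRUE))
  exact_ll <- function(sig, beta) {
    s <- 0
    for (cl in levels(g)) {
      yc <- y[g == cl]
      f <- function(u) sapply(u, function(ui)
        exp(sum(dbinom(yc, 1, plogis(beta + ui), log = TRUE))) *
          dnorm(ui, 0, sig))
      s <- s + log(integrate(f, -Inf, Inf, rel.tol = 1e-12)$value)
    }
    s
  }
  for (sig in c(0.1, 0.15)) for (b in c(0, 0.4)) {
    laplace <- -dd(c(sig, b)) / 2
    expect_lt(abs(laplace - exact_ll(sig, b)), 1e-3)
  }
})

test_that("log-likelihood never decreases when a term is added", {
  f0 <- fit_mixed_logit(cohort360, "bacteremia", character(),
                        grouping = "patient", allow_fallback = FALSE)
  f1 <- fit_mixed_logit(cohort360, "bacteremia", "leucocyte_lt_0_3",
                        grouping = "patient", allow_fallback = FALSE)
  f2 <- fit_mixed_logit(cohort360, "bacteremia",
                        c("leucocyte_lt_0_3", "severely_reduced_general_condition"),
                        grouping = "patient", allow_fallback = FALSE)
  expect_gte(f1$logLik, f0$logLik)
  expect_gte(f2$logLik, f1$logLik)
})

test_that("odds ratios and CIs are consistent with the coefficients", {
  fit <- fit_mixed_logit(cohort360, "bacteremia", "leucocyte_lt_0_3",
                         grouping = "patient")
  expect_equal(fit$or, exp(fit$coefficients), tolerance = 1e-10)
  expect_true(all(fit$or_ci[, "lower"] <= fit$or &
                    fit$or <= fit$or_ci[, "upper"]))
  expect_lte(fit$levels_used, 2)
})

test_that("univariable screen controls type-I error under the null", {
  zero_spec <- list(bacteremia = list(sex = 0), smc = list(sex = 0))
  cfg <- cohort_config(sigma_center = 0, sigma_patient = 0,
                       outcome_coefficients = zero_spec, seed = 0L)
  # episode-level characteristics with moderate prevalence; the Wald test
  # is discretely conservative for rare patient-level covariates at n=360
  chars <- c("season_spring_summer", "out_of_office_presentation",
             "chemo_intensity_above_ALL_maintenance", "sirs_at_presentation")
  hits <- matrix(0, 200, length(chars), dimnames = list(NULL, chars))
  for (i in 1:200) {
    cfg$seed <- 700L + i
    d <- generate_cohort(cfg)
    scr <- univariable_screen(d, "bacteremia", chars, grouping = "none")
    hits[i, scr$significant] <- 1
  }
  rates <- colMeans(hits)
  expect_true(all(rates >= 0.01 & rates <= 0.10),
              info = paste(names(rates), rates, collapse = "; "))
})

test_that("univariable screen detects a strong association", {
  spec <- list(bacteremia = list(severely_reduced_general_condition = log(5)),
               smc = list(sex = 0))
  cfg <- cohort_config(outcome_coefficients = spec, seed = 0L)
  sel <- 0
  for (i in 1:100) {
    cfg$seed <- 800L + i
    d <- generate_cohort(cfg)
    scr <- univariable_screen(d, "bacteremia",
                              c("severely_reduced_general_condition", "sex"),
                              grouping = "none")
    if ("severely_reduced_general_condition" %in% scr$significant)
      sel <- sel + 1
  }
  expect_gt(sel / 100, 0.8)
})

test_that("alpha = 1 returns every evaluable characteristic", {
  scr <- univariable_screen(cohort360, "bacteremia",
                            c("sex", "cvad", "malignancy_type"),
                            alpha = 1.0, grouping = "none")
  expect_setequal(scr$significant,
                  scr$results$characteristic[scr$results$evaluable])
})

test_that("interaction screen: null rejection rate and precondition", {
  zero_spec <- list(bacteremia = list(sex = 0), smc = list(sex = 0))
  cfg <- cohort_config(sigma_center = 0, sigma_patient = 0,
                       outcome_coefficients = zero_spec, seed = 0L)
  rej <- 0
  for (i in 1:100) {
    cfg$seed <- 900L + i
    d <- generate_cohort(cfg)
    out <- interaction_screen(d, "bacteremia",
                              "severely_reduced_general_condition",
                              grouping = "none")
    if (out$significant) rej <- rej + 1
  }
  expect_lte(rej / 100, 0.05)

  d1 <- cohort360[cohort360$randomized_fever_limit == 38.5, ]
  expect_error(interaction_screen(d1, "bacteremia", "sex"),
               "single level")
})

test_that("interaction screen detects a strong simulated interaction", {
  cfg <- cohort_config(n_patients = 880L, sigma_center = 0,
                       sigma_patient = 0, seed = 0L)
  cfg$intercepts <- c(bacteremia = -2, smc = -4)
  hits <- 0
  for (i in 1:50) {
    cfg$seed <- 1100L + i
    d <- generate_cohort(cfg)
    # outcome rebuilt with a log-odds difference of 2 between fever limits
    set.seed(2000L + i)
    eta <- -2 + 2 * d$severely_reduced_general_condition *
      (d$randomized_fever_limit == 39.0)
    d$bacteremia <- rbinom(nrow(d), 1, plogis(eta))
    d$sre <- as.integer(d$bacteremia | d$smc)
    out <- interaction_screen(d, "bacteremia",
                              "severely_reduced_general_condition",
                              grouping = "none")
    if (out$significant) hits <- hits + 1
  }
  expect_gt(hits / 50, 0.8)
})
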