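# Expected integer weights below are hand-derived from the published
# multivariable coefficients with the rule "double, round half away from
# zero, then raise each block's minimum to zero".

test_that("weight derivation reproduces the published score tables", {
  ref <- fn_reference_coefficients()

  bact <- derive_weights(ref$bacteremia, "bacteremia")
  expect_equal(bact$weights$severely_reduced_general_condition[["1"]], 3L)
  expect_equal(bact$weights$bone_marrow_involvement[["1"]], 3L)
  expect_equal(bact$weights$leucocyte_lt_0_3[["1"]], 3L)
  expect_equal(bact$weights$malignancy_type,
               c(ALL = 5L, AML = 8L, Hodgkin = 4L, NHL = 4L,
                 CNS_tumor = 0L, other_solid = 2L))
  expect_equal(bact$offsets[["malignancy_type"]], 5L)
  expect_equal(bact$max_score, 17L)

  smc <- derive_weights(ref$smc, "smc")
  expect_equal(smc$weights$severely_reduced_general_condition[["1"]], 4L)
  expect_equal(smc$weights$platelet_lt_50[["1"]], 2L)
  expect_equal(smc$max_score, 6L)

  sre <- derive_weights(ref$sre, "sre")
  expect_equal(sre$weights$severely_reduced_general_condition[["1"]], 4L)
  expect_equal(sre$weights$bone_marrow_involvement[["1"]], 2L)
  expect_equal(sre$weights$leucocyte_lt_0_3[["1"]], 3L)
  expect_equal(sre$weights$malignancy_type,
               c(ALL = 4L, AML = 6L, Hodgkin = 2L, NHL = 3L,
                 CNS_tumor = 0L, other_solid = 1L))
  expect_equal(sre$offsets[["malignancy_type"]], 4L)
  expect_equal(sre$max_score, 15L)
})

test_that("negative binary weights are offset within their own block", {
  sc <- derive_weights(list(x = -0.6), "bacteremia")
  expect_equal(sc$weights$x, c(`0` = 1L, `1` = 0L))
  expect_equal(sc$offsets[["x"]], 1L)
  expect_equal(sc$max_score, 1L)

  sc0 <- derive_weights(list(x = 0), "bacteremia")
  expect_equal(sc0$weights$x, c(`0` = 0L, `1` = 0L))
})

test_that("weight derivation refuses non-finite and continuous inputs", {
  expect_error(derive_weights(list(x = Inf)), "non-finite")
  fit <- fit_mixed_logit(cohort360, "bacteremia", "hemoglobin",
                         grouping = "none")
  expect_error(derive_weights(fit), "hemoglobin")
})

test_that("score application reproduces worked examples", {
  bact <- derive_weights(fn_reference_coefficients()$bacteremia, "bacteremia")
  # AML + severely reduced condition + leucocytes 0.2 G/L, no marrow involvement
  e1 <- episode_stub(1, malignancy_type = "AML",
                     severely_reduced_general_condition = 1L,
                     leucocyte_count = 0.2, anc = 0.05)
  expect_equal(apply_score(bact, e1), 14L)
  # CNS tumor, no flags
  e2 <- episode_stub(1, malignancy_type = "CNS_tumor")
  expect_equal(apply_score(bact, e2), 0L)

  # SMC score takes only values {0, 2, 4, 6}: exhaustive over the 4 combos
  smc <- derive_weights(fn_reference_coefficients()$smc, "smc")
  combos <- episode_stub(4,
    severely_reduced_general_condition = c(0L, 1L, 0L, 1L),
    platelet_count = c(120, 120, 20, 20))
  expect_equal(apply_score(smc, combos), c(0L, 4L, 2L, 6L))

  expect_error(apply_score(bact, e1[, setdiff(names(e1), "malignancy_type")]),
               "malignancy_type")
})

test_that("threshold calibration reproduces the published choices from the printed counts", {
  # score vectors reconstructed so that TP/TN per threshold equal Table-2
  # style counts of the bacteremia and SMC rules
  bact_scores <- c(rep(6, 42), rep(5, 12), rep(4, 2),       # positives
                   rep(6, 78), rep(5, 129), rep(4, 22), rep(3, 21), rep(2, 54))
  bact_flags <- rep(c(1, 0), c(56, 304))
  thr <- calibrate_threshold(bact_scores, bact_flags)
  expect_equal(as.integer(thr), 5L)
  expect_equal(attr(thr, "sensitivity"), 54 / 56)

  smc_scores <- c(rep(0, 2), rep(2, 14), rep(4, 14),        # positives
                  rep(4, 38), rep(2, 143), rep(0, 149))
  smc_flags <- rep(c(1, 0), c(30, 330))
  expect_equal(as.integer(calibrate_threshold(smc_scores, smc_flags)), 2L)

  # published per-threshold sensitivities select the printed thresholds
  expect_equal(threshold_from_sensitivities(2:5, c(98.6, 98.6, 93.1, 73.6),
                                            min_sensitivity = 90), 4L)
  expect_equal(threshold_from_sensitivities(3:6, c(100, 100, 96.4, 75.0),
                                            min_sensitivity = 90), 5L)
})

test_that("degenerate threshold cases behave as specified", {
  # single positive carrying the maximal score
  thr <- calibrate_threshold(c(0, 1, 5), c(0, 0, 1))
  expect_equal(as.integer(thr), 5L)
  expect_error(calibrate_threshold(c(1, 2), c(0, 0)), "no positive")
  # nothing but the all-high threshold reaches the target
  thr2 <- calibrate_threshold(c(0, 0, 1, 1), c(1, 1, 0, 1),
                              min_sensitivity = 0.9)
  expect_equal(as.integer(thr2), 0L)
  expect_true(attr(thr2, "all_high"))
})

test_that("sensitivity is non-increasing and specificity non-decreasing in the threshold", {
  set.seed(31)
  for (i in 1:20) {
    s <- sample(0:10, 200, replace = TRUE)
    y <- rbinom(200, 1, 0.2)
    if (sum(y) == 0) next
    sens <- sapply(0:11, function(t) mean(s[y == 1] >= t))
    spec <- sapply(0:11, function(t) mean(s[y == 0] < t))
    expect_true(all(diff(sens) <= 1e-12))
    expect_true(all(diff(spec) >= -1e-12))
    tab <- threshold_performance_table(s, y)
    expect_true(all(diff(tab$sensitivity) <= 1e-9))
    expect_true(all(diff(tab$specificity) >= -1e-9))
  }
})

test_that("forward selection: no entries at alpha 0 and few under the null", {
  chars <- c("sex", "cvad", "relapse", "season_spring_summer",
             "out_of_office_presentation", "urti")
  sel <- forward_select(cohort360, "bacteremia", chars, alpha_entry = 0,
                        guard_reps = 2, seed = 1, grouping = "none")
  expect_length(sel$selected, 0)

  zero_spec <- list(bacteremia = list(sex = 0), smc = list(sex = 0))
  cfg <- cohort_config(sigma_center = 0, sigma_patient = 0,
                       outcome_coefficients = zero_spec, seed = 0L)
  sizes <- sapply(1:60, function(i) {
    cfg$seed <- 1300L + i
    d <- generate_cohort(cfg)
    length(forward_select(d, "bacteremia", chars, guard_reps = 5,
                          seed = i, grouping = "none")$selected)
  })
  expect_lte(mean(sizes), 1)
})

test_that("forward selection recovers strong true predictors", {
  sel <- forward_select(cohort2000, "bacteremia",
                        c("severely_reduced_general_condition",
                          "leucocyte_lt_0_3", "bone_marrow_involvement",
                          "malignancy_type", "sex", "cvad"),
                        guard_reps = 10, seed = 4, grouping = "none")
  expect_true(all(c("severely_reduced_general_condition", "leucocyte_lt_0_3",
                    "bone_marrow_involvement", "malignancy_type")
                  %in% sel$selected))
  expect_true(all(c("step", "characteristic", "p_entry", "median_cv_auroc",
                    "action") %in% names(sel$step_log)))
})

test_that("internal CV is exact on a perfectly separating score and deterministic", {
  d <- episode_stub(40, bacteremia = rep(c(0L, 1L), each = 20),
                    severely_reduced_general_condition = rep(c(0L, 1L), each = 20),
                    patient_id = 1:40)
  cv <- internal_cv(d, "bacteremia", "severely_reduced_general_condition",
                    reps = 2, folds = 2, seed = 9, engine = "glm")
  s <- cv$summary
  expect_equal(s$median[s$metric == "sensitivity"], 100)
  expect_equal(s$median[s$metric == "specificity"], 100)
  cv2 <- internal_cv(d, "bacteremia", "severely_reduced_general_condition",
                     reps = 2, folds = 2, seed = 9, engine = "glm")
  expect_identical(cv, cv2)
})

test_that("cross-validated sensitivity sits inside the resubstitution CI and shows no negative optimism", {
  terms <- c("severely_reduced_general_condition", "leucocyte_lt_0_3",
             "bone_marrow_involvement", "malignancy_type")
  fit <- fit_mixed_logit(cohort2000, "bacteremia", terms, grouping = "patient")
  sc <- derive_weights(fit)
  scores <- apply_score(sc, cohort2000)
  thr <- calibrate_threshold(scores, cohort2000$bacteremia)
  resub <- performance(confusion_matrix(scores >= thr, cohort2000$bacteremia))
  m <- resub$metrics
  cv <- internal_cv(cohort2000, "bacteremia", terms, reps = 20, folds = 10,
                    seed = 13, engine = "glm")
  cv_sens <- cv$summary$median[cv$summary$metric == "sensitivity"]
  cv_spec <- cv$summary$median[cv$summary$metric == "specificity"]
  expect_gte(cv_sens, m$lower[m$metric == "sensitivity"])
  expect_lte(cv_sens, m$upper[m$metric == "sensitivity"])
  # optimism is non-negative in expectation (small tolerance for noise)
  expect_lte(cv_spec, m$estimate[m$metric == "specificity"] + 5)
  expect_equal(cv$dropped, 0)
})
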