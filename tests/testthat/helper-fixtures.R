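# Shared fixtures, built in code. Expensive objects are created once per
# test run.

# Default-configuration cohort (≈360 episodes) with intercepts calibrated
# once and reused.
default_config <- cohort_config(seed = 101L)
default_intercepts <- calibrate_intercepts(default_config)
default_config$intercepts <- default_intercepts

cohort360 <- local({
  generate_cohort(default_config)
})

# Larger cohort (≈2000 episodes) from the published bacteremia/SMC
# generative coefficients, for fits that need sample size.
config2000 <- local({
  cfg <- cohort_config(n_patients = 880L, seed = 202L)
  cfg$intercepts <- calibrate_intercepts(cfg)
  cfg
})
cohort2000 <- generate_cohort(config2000)

# One fully specified schema-valid episode row; override any field via ...
episode_stub <- function(n = 1, ...) {
  d <- data.frame(
    center_id = 1L, patient_id = seq_len(n), episode_index = 1L,
    sex = 1L, age_years = 7, age_group = "6-11", malignancy_type = "ALL",
    relapse = 0L, chemo_intensity_above_ALL_maintenance = 0L, cvad = 1L,
    bone_marrow_involvement = 0L, months_since_diagnosis = 6,
    prior_fn_count = 0L, prior_fn_bacteremia_count = 0L,
    season_spring_summer = 0L, out_of_office_presentation = 0L,
    temperature_at_presentation = 38.6,
    severely_reduced_general_condition = 0L, sirs_at_presentation = 0L,
    randomized_fever_limit = 38.5, hemoglobin = 85, leucocyte_count = 1.2,
    anc = 0.3, amc = 0.2, platelet_count = 120, new_diagnosis = 0L,
    hsct_history = 0L, clinical_site_infection = 0L, urti = 0L,
    inpatient_onset = 0L, bacteremia = 0L, smc = 0L, sre = 0L,
    stringsAsFactors = FALSE
  )
  ov <- list(...)
  for (nm in names(ov)) d[[nm]] <- ov[[nm]]
  d$sre <- as.integer(d$bacteremia | d$smc)
  d
}

# The exact closed form of prop.test's one-sample continuity-corrected
# Wilson interval (continuity correction capped at |x - n/2|), written
# independently of the package.
wilson_cc_oracle <- function(x, n, conf = 0.95) {
  z <- qnorm((1 + conf) / 2)
  yates <- min(0.5, abs(x - n * 0.5))
  z22n <- z^2 / (2 * n)
  est <- x / n
  p.c <- est + yates / n
  upper <- if (p.c >= 1) 1 else
    (p.c + z22n + z * sqrt(p.c * (1 - p.c) / n + z22n / (2 * n))) / (1 + 2 * z22n)
  p.c <- est - yates / n
  lower <- if (p.c <= 0) 0 else
    (p.c + z22n - z * sqrt(p.c * (1 - p.c) / n + z22n / (2 * n))) / (1 + 2 * z22n)
  c(lower, upper)
}

# Yates-corrected 2x2 chi-square test of equal proportions, written from
# the textbook table formula (correction capped at |O - E|).
two_prop_oracle <- function(x1, n1, x2, n2) {
  O <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  yates <- min(0.5, abs(O[1, 1] - E[1, 1]))
  stat <- sum((abs(O - E) - yates)^2 / E)
  pchisq(stat, 1, lower.tail = FALSE)
}
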