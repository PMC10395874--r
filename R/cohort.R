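#' Episode table schema
#'
#' Column names and types of the fever-in-neutropenia (FN) episode table:
#' one row per episode, identifiers for center and patient, the 15 clinical
#' and 5 hematological presentation characteristics, auxiliary fields needed
#' by the published rules and their eligibility filters, and the three binary
#' outcomes (bacteremia, serious medical complication, safety relevant event).
#'
#' @return A data frame with columns `column` and `type` (`"integer"`,
#'   `"numeric"` or `"character"`).
#' @export
fn_episode_schema <- function() {
  s <- rbind(
    c("center_id", "integer"),
    c("patient_id", "integer"),
    c("episode_index", "integer"),
    c("sex", "integer"),
    c("age_years", "numeric"),
    c("age_group", "character"),
    c("malignancy_type", "character"),
    c("relapse", "integer"),
    c("chemo_intensity_above_ALL_maintenance", "integer"),
    c("cvad", "integer"),
    c("bone_marrow_involvement", "integer"),
    c("months_since_diagnosis", "numeric"),
    c("prior_fn_count", "integer"),
    c("prior_fn_bacteremia_count", "integer"),
    c("season_spring_summer", "integer"),
    c("out_of_office_presentation", "integer"),
    c("temperature_at_presentation", "numeric"),
    c("severely_reduced_general_condition", "integer"),
    c("sirs_at_presentation", "integer"),
    c("randomized_fever_limit", "numeric"),
    c("hemoglobin", "numeric"),
    c("leucocyte_count", "numeric"),
    c("anc", "numeric"),
    c("amc", "numeric"),
    c("platelet_count", "numeric"),
    c("new_diagnosis", "integer"),
    c("hsct_history", "integer"),
    c("clinical_site_infection", "integer"),
    c("urti", "integer"),
    c("inpatient_onset", "integer"),
    c("bacteremia", "integer"),
    c("smc", "integer"),
    c("sre", "integer")
  )
  data.frame(column = s[, 1], type = s[, 2], stringsAsFactors = FALSE)
}

malignancy_levels <- function() {
  c("ALL", "AML", "Hodgkin", "NHL", "CNS_tumor", "other_solid")
}

age_group_levels <- function() c("<6", "6-11", ">=12")

#' Synthetic cohort configuration
#'
#' Builds and validates the configuration of the synthetic FN cohort
#' generator. Defaults emulate the multicenter study design the pipeline is
#' built for: 6 centers, 158 patients, about 360 episodes (1 to 6 per
#' patient, median 2, IQR 1 to 3), marginal outcome rates 15.6% bacteremia
#' and 8.3% SMC (SRE, their union, then lands near 20%), and clustered risk
#' through Gaussian random intercepts on the logit scale for centers and for
#' patients.
#'
#' @param n_centers number of centers.
#' @param n_patients number of patients (must be >= `n_centers`).
#' @param episode_count_distribution probability mass over 1..6 episodes per
#'   patient.
#' @param sigma_center SD of the center random intercept (logit scale).
#' @param sigma_patient SD of the patient random intercept (logit scale).
#' @param covariate_params named list of per-characteristic distribution
#'   parameters; unspecified entries fall back to the documented defaults
#'   (see `default_covariate_params()`).
#' @param outcome_coefficients list with elements `bacteremia` and `smc`,
#'   each a coefficient specification (named list: binary characteristics map
#'   to a scalar log-odds coefficient, `malignancy_type` to a named vector
#'   over its six levels). Defaults are the published multivariable
#'   coefficients of the bacteremia and SMC risk models
#'   (see [fn_reference_coefficients()]).
#' @param target_prevalences named vector `c(bacteremia=, smc=)` of marginal
#'   outcome rates the intercepts are calibrated to.
#' @param smc_given_bacteremia_boost additional log-odds of SMC when
#'   bacteremia is present; the default 1.8 makes the expected
#'   bacteremia-and-SMC overlap about 14 of 360 episodes, so that SRE counts
#'   are internally consistent with the marginal rates.
#' @param intercepts optional named vector `c(bacteremia=, smc=)` of
#'   pre-calibrated intercepts; if `NULL`, [generate_cohort()] calibrates
#'   them by Monte-Carlo bisection.
#' @param seed integer master seed; covariates, random intercepts and outcome
#'   draws use separate named substreams of it.
#' @return A list of class `fn_cohort_config`.
#' @export
cohort_config <- function(n_centers = 6L,
                          n_patients = 158L,
                          episode_count_distribution = c(0.37, 0.28, 0.17, 0.10, 0.05, 0.03),
                          sigma_center = 0.3,
                          sigma_patient = 0.8,
                          covariate_params = list(),
                          outcome_coefficients = NULL,
                          target_prevalences = c(bacteremia = 0.156, smc = 0.083),
                          smc_given_bacteremia_boost = 1.8,
                          intercepts = NULL,
                          seed = 1L) {
  if (is.null(outcome_coefficients)) {
    ref <- fn_reference_coefficients()
    outcome_coefficients <- list(bacteremia = ref$bacteremia, smc = ref$smc)
  }
  cp <- utils::modifyList(default_covariate_params(), covariate_params)
  cfg <- structure(list(
    n_centers = as.integer(n_centers),
    n_patients = as.integer(n_patients),
    episode_count_distribution = episode_count_distribution,
    sigma_center = sigma_center,
    sigma_patient = sigma_patient,
    covariate_params = cp,
    outcome_coefficients = outcome_coefficients,
    target_prevalences = target_prevalences,
    smc_given_bacteremia_boost = smc_given_bacteremia_boost,
    intercepts = intercepts,
    seed = as.integer(seed)
  ), class = "fn_cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Default covariate distribution parameters
#'
#' The covariate marginals are free parameters of the generator (the study's
#' joint covariate distribution is not public); these defaults are chosen to
#' be clinically plausible for a pediatric oncology FN cohort: ALL the most
#' common malignancy, most patients with a central venous access device,
#' blood counts log-normal on the scale of chemotherapy-induced cytopenia.
#'
#' @return named list of parameters consumed by [generate_cohort()].
#' @export
default_covariate_params <- function() {
  list(
    center_probs = c(0.30, 0.20, 0.15, 0.15, 0.12, 0.08),
    malignancy_probs = c(ALL = 0.45, AML = 0.08, Hodgkin = 0.05, NHL = 0.08,
                         CNS_tumor = 0.09, other_solid = 0.25),
    age_shape = 2, age_scale = 3.5,          # gamma, years; median ~6, IQR ~3-10
    p_sex_male = 0.55,
    p_relapse = 0.12,
    p_hsct_history = 0.05,
    p_cvad = 0.85,
    p_chemo_intensity = 0.60,
    p_bmi_leukemia_lymphoma = 0.15,          # bone marrow involvement
    p_bmi_solid = 0.02,
    p_srgc = 0.12,                           # severely reduced general condition
    p_sirs = 0.15,
    p_season = 0.50,
    p_out_of_office = 0.40,
    p_clinical_site_infection = 0.15,
    p_urti = 0.20,
    p_inpatient_onset = 0.10,
    temp_mean = 38.9, temp_sd = 0.5,
    hb_mean = 85, hb_sd = 15,                # g/L
    leuco_meanlog = 0, leuco_sdlog = 1.1,    # G/L
    anc_frac_shape1 = 1.2, anc_frac_shape2 = 4,
    amc_frac_shape1 = 1, amc_frac_shape2 = 6,
    platelet_meanlog = log(100), platelet_sdlog = 0.9,
    months_shape = 1.5, months_scale = 8,
    prior_fn_rate = 0.3,                     # extra pre-study FN episodes
    p_prior_fn_bacteremia = 0.2
  )
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (length(cfg$n_centers) != 1 || is.na(cfg$n_centers) || cfg$n_centers < 1)
    fail("n_centers", "must be a positive integer")
  if (cfg$n_patients < cfg$n_centers)
    fail("n_patients", "must be >= n_centers")
  p <- cfg$episode_count_distribution
  if (length(p) != 6 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    fail("episode_count_distribution", "must be 6 non-negative masses summing to 1")
  if (cfg$sigma_center < 0) fail("sigma_center", "must be >= 0")
  if (cfg$sigma_patient < 0) fail("sigma_patient", "must be >= 0")
  tp <- cfg$target_prevalences
  if (!all(c("bacteremia", "smc") %in% names(tp)))
    fail("target_prevalences", "must name 'bacteremia' and 'smc'")
  if (any(tp <= 0) || any(tp >= 1))
    fail("target_prevalences", "must lie in (0, 1)")
  oc <- cfg$outcome_coefficients
  if (!all(c("bacteremia", "smc") %in% names(oc)))
    fail("outcome_coefficients", "must name 'bacteremia' and 'smc'")
  mp <- cfg$covariate_params$malignancy_probs
  if (abs(sum(mp) - 1) > 1e-8)
    fail("covariate_params$malignancy_probs", "must sum to 1")
  if (length(cfg$seed) != 1 || is.na(cfg$seed))
    fail("seed", "must be a single integer")
  invisible(cfg)
}

#' Read a cohort configuration from YAML
#'
#' Unknown keys are rejected (a misspelled parameter must not silently fall
#' back to its default).
#'
#' @param path YAML file path.
#' @return validated `fn_cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown cohort configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$target_prevalences))
    raw$target_prevalences <- unlist(raw$target_prevalences)
  if (!is.null(raw$intercepts)) raw$intercepts <- unlist(raw$intercepts)
  do.call(cohort_config, raw)
}

# Simulate the structural part of a cohort: centers, patients, episodes,
# covariates, and per-episode outcome random-intercept sums. Intercept-free
# linear predictors for both generated outcomes are returned so intercept
# calibration and outcome drawing share one code path.
simulate_structure <- function(cfg, seed, n_patients = cfg$n_patients) {
  cp <- cfg$covariate_params
  set.seed(seed)

  ncen <- cfg$n_centers
  cen_probs <- if (length(cp$center_probs) == ncen) cp$center_probs
               else rep(1 / ncen, ncen)
  center_of_patient <- sort(sample.int(ncen, n_patients, replace = TRUE,
                                       prob = cen_probs))
  # cluster-randomized fever limit: alternate limits over centers
  limit_of_center <- rep(c(38.5, 39.0), length.out = ncen)

  n_ep <- sample(1:6, n_patients, replace = TRUE,
                 prob = cfg$episode_count_distribution)
  pid <- rep(seq_len(n_patients), n_ep)
  n <- length(pid)
  epi <- sequence(n_ep)

  # patient-level covariates
  malig <- sample(malignancy_levels(), n_patients, replace = TRUE,
                  prob = cp$malignancy_probs)
  age <- pmin(17, pmax(1, round(stats::rgamma(n_patients, cp$age_shape,
                                              scale = cp$age_scale))))
  sex <- stats::rbinom(n_patients, 1, cp$p_sex_male)
  relapse <- stats::rbinom(n_patients, 1, cp$p_relapse)
  hsct <- stats::rbinom(n_patients, 1, cp$p_hsct_history)
  cvad <- stats::rbinom(n_patients, 1, cp$p_cvad)
  base_months <- stats::rgamma(n_patients, cp$months_shape, scale = cp$months_scale)
  prior_base <- stats::rpois(n_patients, cp$prior_fn_rate)

  p_bmi <- ifelse(malig %in% c("ALL", "AML", "NHL", "Hodgkin"),
                  cp$p_bmi_leukemia_lymphoma, cp$p_bmi_solid)
  bmi <- stats::rbinom(n_patients, 1, p_bmi)

  # episode-level covariates
  chemo <- stats::rbinom(n, 1, cp$p_chemo_intensity)
  srgc <- stats::rbinom(n, 1, cp$p_srgc)
  sirs <- stats::rbinom(n, 1, cp$p_sirs)
  season <- stats::rbinom(n, 1, cp$p_season)
  ooo <- stats::rbinom(n, 1, cp$p_out_of_office)
  csi <- stats::rbinom(n, 1, cp$p_clinical_site_infection)
  urti <- stats::rbinom(n, 1, cp$p_urti)
  inpat <- stats::rbinom(n, 1, cp$p_inpatient_onset)
  temp <- pmax(37.5, round(stats::rnorm(n, cp$temp_mean, cp$temp_sd), 1))
  hb <- pmax(40, round(stats::rnorm(n, cp$hb_mean, cp$hb_sd)))
  leuco <- round(stats::rlnorm(n, cp$leuco_meanlog, cp$leuco_sdlog), 3)
  anc <- round(leuco * stats::rbeta(n, cp$anc_frac_shape1, cp$anc_frac_shape2), 3)
  anc <- pmin(anc, leuco)
  amc <- round((leuco - anc) * stats::rbeta(n, cp$amc_frac_shape1, cp$amc_frac_shape2), 3)
  plt <- pmax(1, round(stats::rlnorm(n, cp$platelet_meanlog, cp$platelet_sdlog)))
  months <- round(base_months[pid] + 1.5 * (epi - 1), 1)
  prior_fn <- prior_base[pid] + (epi - 1L)
  prior_fn_bact <- stats::rbinom(n, prior_fn, cp$p_prior_fn_bacteremia)

  d <- data.frame(
    center_id = center_of_patient[pid],
    patient_id = pid,
    episode_index = epi,
    sex = sex[pid],
    age_years = age[pid],
    age_group = as.character(cut(age[pid], c(-Inf, 5.5, 11.5, Inf),
                                 labels = age_group_levels())),
    malignancy_type = malig[pid],
    relapse = relapse[pid],
    chemo_intensity_above_ALL_maintenance = chemo,
    cvad = cvad[pid],
    bone_marrow_involvement = bmi[pid],
    months_since_diagnosis = months,
    prior_fn_count = prior_fn,
    prior_fn_bacteremia_count = prior_fn_bact,
    season_spring_summer = season,
    out_of_office_presentation = ooo,
    temperature_at_presentation = temp,
    severely_reduced_general_condition = srgc,
    sirs_at_presentation = sirs,
    randomized_fever_limit = limit_of_center[center_of_patient[pid]],
    hemoglobin = hb,
    leucocyte_count = leuco,
    anc = anc,
    amc = amc,
    platelet_count = plt,
    new_diagnosis = as.integer(months < 2),
    hsct_history = hsct[pid],
    clinical_site_infection = csi,
    urti = urti,
    inpatient_onset = inpat,
    stringsAsFactors = FALSE
  )

  # random intercepts: independent per outcome, shared across a patient's
  # episodes (and a center's patients)
  set.seed(substream(seed, 11L))
  re <- list()
  for (oc in c("bacteremia", "smc")) {
    u <- stats::rnorm(ncen, 0, cfg$sigma_center)
    v <- stats::rnorm(n_patients, 0, cfg$sigma_patient)
    re[[oc]] <- u[d$center_id] + v[d$patient_id]
  }

  lp <- list(
    bacteremia = coefspec_lp(cfg$outcome_coefficients$bacteremia, d),
    smc = coefspec_lp(cfg$outcome_coefficients$smc, d)
  )
  list(data = d, lp = lp, re = re,
       eta = list(bacteremia = lp$bacteremia + re$bacteremia,
                  smc = lp$smc + re$smc))
}

# Evaluate a coefficient specification (named list: scalar per binary /
# continuous characteristic, named vector per categorical level) as a
# fixed-effects linear predictor without intercept.
coefspec_lp <- function(spec, data) {
  lp <- numeric(nrow(data))
  for (ch in names(spec)) {
    co <- spec[[ch]]
    if (length(co) > 1) {
      lev <- data[[ch]]
      miss <- setdiff(unique(lev), names(co))
      if (length(miss))
        stop("coefficient specification for '", ch, "' lacks level(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      lp <- lp + unname(co[lev])
    } else {
      lp <- lp + co * term_value(data, ch)
    }
  }
  lp
}

bisect_intercept <- function(prev_fun, target, lower = -20, upper = 20,
                             tol = 1e-8) {
  if (prev_fun(lower) > target || prev_fun(upper) < target)
    stop("intercept calibration error: target prevalence ", target,
         " not bracketed in [", lower, ", ", upper, "]", call. = FALSE)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (prev_fun(mid) < target) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

#' Calibrate outcome intercepts by Monte Carlo bisection
#'
#' Finds per-outcome intercepts such that the Monte-Carlo marginal prevalence
#' of bacteremia and SMC matches the configured targets. Marginal prevalence
#' is strictly increasing in the intercept, so a monotone bisection on a
#' fixed Monte-Carlo sample of covariates and random intercepts converges to
#' the unique root. The SMC intercept is calibrated jointly with the
#' bacteremia model: each Monte-Carlo episode's SMC probability is
#' marginalized over its bacteremia status analytically.
#'
#' The Monte-Carlo sample integrates the cluster effects with independent
#' per-episode draws of `N(0, sqrt(sigma_center^2 + sigma_patient^2))`: the
#' clustering itself is irrelevant to a marginal prevalence, and reusing a
#' few shared center draws would leave seed-level noise in the calibration
#' that no sample size removes.
#'
#' @param config `fn_cohort_config`.
#' @param n_mc Monte-Carlo sample size (episodes), at least 10^4.
#' @return named vector `c(bacteremia=, smc=)` of intercepts (log-odds).
#' @export
calibrate_intercepts <- function(config, n_mc = 20000L) {
  validate_cohort_config(config)
  if (n_mc < 1e4) stop("n_mc must be >= 10^4", call. = FALSE)
  npat <- ceiling(n_mc / sum(1:6 * config$episode_count_distribution))
  sim <- simulate_structure(config, seed = substream(config$seed, 901L),
                            n_patients = as.integer(npat))
  n <- nrow(sim$data)
  set.seed(substream(config$seed, 902L))
  sig <- sqrt(config$sigma_center^2 + config$sigma_patient^2)
  eta_b <- sim$lp$bacteremia + stats::rnorm(n, 0, sig)
  eta_s <- sim$lp$smc + stats::rnorm(n, 0, sig)
  tp <- config$target_prevalences
  a_b <- bisect_intercept(function(a) mean(stats::plogis(a + eta_b)),
                          tp[["bacteremia"]])
  p_b <- stats::plogis(a_b + eta_b)
  boost <- config$smc_given_bacteremia_boost
  a_s <- bisect_intercept(function(a) {
    mean(p_b * stats::plogis(a + eta_s + boost) +
           (1 - p_b) * stats::plogis(a + eta_s))
  }, tp[["smc"]])
  c(bacteremia = a_b, smc = a_s)
}

#' Generate a synthetic FN episode cohort
#'
#' Draws a full episode table from the configured multicenter structure:
#' covariates and episode counts from the covariate stream, Gaussian center
#' and patient random intercepts from the random-effect stream, and outcomes
#' from logistic models on the episode covariates plus the random intercepts
#' (outcome uniforms from a third stream, so recalibrating an intercept never
#' perturbs covariates or cluster effects). SRE is computed as the union of
#' bacteremia and SMC.
#'
#' @param config `fn_cohort_config`.
#' @return episode data frame (one row per episode) passing
#'   [validate_episodes()].
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  ic <- config$intercepts %||% calibrate_intercepts(config)
  if (!all(c("bacteremia", "smc") %in% names(ic)))
    stop("invalid cohort configuration: field 'intercepts' must name 'bacteremia' and 'smc'",
         call. = FALSE)
  sim <- simulate_structure(config, seed = substream(config$seed, 1L))
  d <- sim$data
  n <- nrow(d)
  set.seed(substream(config$seed, 21L))
  u_b <- stats::runif(n)
  u_s <- stats::runif(n)
  bact <- as.integer(u_b < stats::plogis(ic[["bacteremia"]] + sim$eta$bacteremia))
  p_smc <- stats::plogis(ic[["smc"]] + sim$eta$smc +
                           config$smc_given_bacteremia_boost * bact)
  smc <- as.integer(u_s < p_smc)
  d$bacteremia <- bact
  d$smc <- smc
  d$sre <- as.integer(bact | smc)
  validate_episodes(d)
  d
}

#' Validate an episode table against the schema and its invariants
#'
#' Checks that every schema column is present, that binary fields are 0/1,
#' and the structural invariants: `sre == bacteremia | smc`, `anc <=
#' leucocyte_count`, non-negative counts, temperature >= 37.5 degrees C,
#' episode index in 1..6, malignancy type constant within patient. Violations
#' are reported with the offending column and row numbers.
#'
#' @param data episode data frame.
#' @return the data, invisibly, if valid; otherwise an error.
#' @export
validate_episodes <- function(data) {
  sch <- fn_episode_schema()
  missing_cols <- setdiff(sch$column, names(data))
  if (length(missing_cols))
    stop("episode table validation error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- function(col, rows, why) {
    if (length(rows))
      stop(sprintf("episode table validation error: column '%s' %s at row(s) %s",
                   col, why, paste(utils::head(rows, 10), collapse = ", ")),
           call. = FALSE)
  }
  binaries <- c("sex", "relapse", "chemo_intensity_above_ALL_maintenance",
                "cvad", "bone_marrow_involvement", "season_spring_summer",
                "out_of_office_presentation", "severely_reduced_general_condition",
                "sirs_at_presentation", "new_diagnosis", "hsct_history",
                "clinical_site_infection", "urti", "inpatient_onset",
                "bacteremia", "smc", "sre")
  for (b in binaries) bad(b, which(!data[[b]] %in% c(0L, 1L)), "is not 0/1")
  bad("sre", which(data$sre != as.integer(data$bacteremia | data$smc)),
      "differs from bacteremia OR smc")
  bad("anc", which(data$anc > data$leucocyte_count + 1e-9), "exceeds leucocyte_count")
  for (cc in c("months_since_diagnosis", "prior_fn_count",
               "prior_fn_bacteremia_count", "hemoglobin", "leucocyte_count",
               "anc", "amc", "platelet_count"))
    bad(cc, which(data[[cc]] < 0), "is negative")
  bad("temperature_at_presentation",
      which(data$temperature_at_presentation < 37.5), "is below 37.5")
  bad("episode_index", which(data$episode_index < 1 | data$episode_index > 6),
      "is outside 1..6")
  bad("malignancy_type",
      which(!data$malignancy_type %in% malignancy_levels()),
      "has an unknown level")
  bad("randomized_fever_limit",
      which(!data$randomized_fever_limit %in% c(38.5, 39.0)),
      "is not 38.5 or 39.0")
  mt <- tapply(data$malignancy_type, data$patient_id,
               function(x) length(unique(x)))
  if (any(mt > 1)) {
    pats <- names(mt)[mt > 1]
    rows <- which(data$patient_id %in% as.integer(pats))
    bad("malignancy_type", rows, "varies within a patient")
  }
  invisible(data)
}

#' Write / read an episode table as CSV
#'
#' UTF-8, comma separated, '.' decimal, fixed header. `read_episodes()`
#' validates the table and reports schema violations with row numbers.
#'
#' @param data episode data frame.
#' @param path file path.
#' @return `read_episodes()` returns the validated episode data frame.
#' @export
write_episodes <- function(data, path) {
  validate_episodes(data)
  sch <- fn_episode_schema()
  utils::write.csv(data[, sch$column], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  sch <- fn_episode_schema()
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(sch$column, names(d))
  if (length(missing_cols))
    stop("episode table validation error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(sch))) {
    col <- sch$column[i]
    d[[col]] <- switch(sch$type[i],
                       integer = as.integer(d[[col]]),
                       numeric = as.numeric(d[[col]]),
                       character = as.character(d[[col]]))
  }
  validate_episodes(d)
  d
}
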