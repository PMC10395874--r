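# Characteristic (model term) registry: the 15 clinical and 5 hematological
# presentation characteristics, including the dichotomized forms the derived
# CDRs use (leucocyte count < 0.3 G/L, platelet count < 50 G/L, temperature
# >= 39 degrees C).

#' Screening characteristics
#'
#' The 20 presentation characteristics entering the univariable screen:
#' 15 clinical and 5 hematological. Blood counts used by the derived scores
#' enter via their dichotomized forms (`leucocyte_lt_0_3`, `platelet_lt_50`);
#' temperature enters as the >= 39 degrees C indicator; hemoglobin, ANC and
#' AMC enter linearly.
#'
#' @return character vector of characteristic names.
#' @export
fn_characteristics <- function() {
  c("sex", "age_group", "malignancy_type", "relapse",
    "chemo_intensity_above_ALL_maintenance", "cvad",
    "bone_marrow_involvement", "months_since_diagnosis", "prior_fn_count",
    "prior_fn_bacteremia_count", "season_spring_summer",
    "out_of_office_presentation", "temp_ge_39",
    "severely_reduced_general_condition", "sirs_at_presentation",
    "hemoglobin", "leucocyte_lt_0_3", "anc", "amc", "platelet_lt_50")
}

term_info <- function(name) {
  categorical <- list(
    age_group = list(levels = age_group_levels(), ref = "<6"),
    malignancy_type = list(levels = malignancy_levels(), ref = "ALL")
  )
  continuous <- c("months_since_diagnosis", "prior_fn_count",
                  "prior_fn_bacteremia_count", "hemoglobin", "anc", "amc")
  if (name %in% names(categorical))
    c(list(type = "categorical"), categorical[[name]])
  else if (name %in% continuous)
    list(type = "continuous")
  else
    list(type = "binary")
}

# Episode table column (possibly derived) for a model term.
term_value <- function(data, name) {
  v <- switch(name,
    leucocyte_lt_0_3 = as.integer(data$leucocyte_count < 0.3),
    platelet_lt_50 = as.integer(data$platelet_count < 50),
    temp_ge_39 = as.integer(data$temperature_at_presentation >= 39),
    anc_lt_0_1 = as.integer(data$anc < 0.1),
    data[[name]]
  )
  if (is.null(v))
    stop("input error: episode table lacks characteristic '", name, "'",
         call. = FALSE)
  info <- term_info(name)
  if (info$type == "categorical")
    v <- factor(v, levels = c(info$ref, setdiff(info$levels, info$ref)))
  v
}

# Model frame for a fit: outcome, grouping ids, one column per term.
build_model_frame <- function(data, outcome, terms) {
  if (!outcome %in% c("bacteremia", "smc", "sre"))
    stop("input error: unknown outcome '", outcome, "'", call. = FALSE)
  mf <- data.frame(.y = data[[outcome]],
                   .center = factor(data$center_id),
                   .patient = factor(data$patient_id))
  for (t in terms) mf[[t]] <- term_value(data, t)
  mf
}
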