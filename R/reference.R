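#' Published multivariable coefficients of the SPOG 2015 FN risk models
#'
#' The multivariable mixed-logistic-regression coefficients (log-odds scale)
#' reported for the three derived CDRs in the SPOG 2015 FN definition study
#' cohort: bacteremia and SRE models with four characteristics (severely
#' reduced general condition, bone marrow involvement, leucocyte count
#' < 0.3 G/L, type of malignancy with ALL as reference), the SMC model with
#' two (severely reduced general condition, platelet count < 50 G/L).
#'
#' These serve two purposes: they are the default generative coefficients of
#' the synthetic cohort, and feeding them through [derive_weights()]
#' reproduces the published integer score weights (maxima 17, 6 and 15
#' points).
#'
#' @return list with elements `bacteremia`, `smc`, `sre`; each a coefficient
#'   specification (named list; `malignancy_type` is a named vector over its
#'   six levels, reference ALL at 0).
#' @export
fn_reference_coefficients <- function() {
  malig_bact <- c(ALL = 0, AML = 1.27, Hodgkin = -0.30, NHL = -0.56,
                  CNS_tumor = -2.58, other_solid = -1.52)
  malig_sre <- c(ALL = 0, AML = 0.85, Hodgkin = -0.89, NHL = -0.74,
                 CNS_tumor = -1.85, other_solid = -1.60)
  list(
    bacteremia = list(
      severely_reduced_general_condition = 1.56,
      bone_marrow_involvement = 1.41,
      leucocyte_lt_0_3 = 1.69,
      malignancy_type = malig_bact
    ),
    smc = list(
      severely_reduced_general_condition = 1.90,
      platelet_lt_50 = 1.11
    ),
    sre = list(
      severely_reduced_general_condition = 1.84,
      bone_marrow_involvement = 1.23,
      leucocyte_lt_0_3 = 1.54,
      malignancy_type = malig_sre
    )
  )
}

#' Published per-threshold confusion counts of the derived CDRs
#'
#' The (TP, TN, FP, FN) counts reported for each candidate score threshold of
#' the three derived CDRs on the 360-episode derivation cohort. Used to
#' exercise threshold calibration and the performance/CI machinery against
#' printed values, and as the derivation-dataset side of worked examples.
#'
#' @return data frame with columns `outcome`, `threshold`, `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
fn_reference_threshold_counts <- function() {
  d <- rbind(
    c("bacteremia", 3, 56, 54, 250, 0),
    c("bacteremia", 4, 56, 75, 229, 0),
    c("bacteremia", 5, 54, 97, 207, 2),
    c("bacteremia", 6, 42, 226, 78, 14),
    c("smc", 1, 28, 149, 181, 2),
    c("smc", 2, 28, 149, 181, 2),
    c("smc", 3, 14, 292, 38, 16),
    c("sre", 2, 71, 53, 235, 1),
    c("sre", 3, 71, 58, 230, 1),
    c("sre", 4, 67, 93, 195, 5),
    c("sre", 5, 53, 217, 71, 19),
    c("sre", 6, 50, 220, 68, 22)
  )
  out <- data.frame(outcome = d[, 1], stringsAsFactors = FALSE)
  for (i in seq_along(c("threshold", "tp", "tn", "fp", "fn")))
    out[[c("threshold", "tp", "tn", "fp", "fn")[i]]] <- as.integer(d[, i + 1])
  out
}
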