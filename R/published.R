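# Registry of the eleven published pediatric FN clinical decision rules used
# for external validation, their restricted-validation-dataset (rVD)
# eligibility filters, and the external-validation harness.

need_cols <- function(data, cols, rule) {
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("input error: rule '", rule, "' requires predictor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Registry of published CDRs
#'
#' One entry per rule: risk-tier function, tier levels, default target
#' outcome on this schema, and the eligibility filter reconstructing each
#' publication's in-/exclusion criteria to the extent the schema represents
#' them. The three `aus_*` variants share one tier function and differ only
#' in target outcome. Default target-outcome mapping (overridable in
#' [validate_cdr()]): bacteremia-type outcomes map to the bacteremia flag,
#' composite infection/adverse-event outcomes to SRE, organ-support-type
#' outcomes (Suttitossatam severe adverse outcomes, AUS ICU admission) to
#' SMC.
#'
#' @return named list of rule descriptors (id, label, tiers, target,
#'   classify, restrict, restrict_desc).
#' @export
published_cdrs <- function() {
  reg <- list()

  reg$rackoff <- list(
    label = "Rackoff 1996", tiers = c("low", "intermediate", "high"),
    target = "bacteremia",
    classify = function(d) {
      need_cols(d, c("amc", "temperature_at_presentation"), "rackoff")
      ifelse(d$amc < 0.1 & d$temperature_at_presentation >= 39, "high",
             ifelse(d$amc < 0.1, "intermediate", "low"))
    },
    restrict = function(d) d$inpatient_onset == 0,
    restrict_desc = "exclude inpatient-onset FN")

  reg$klaassen <- list(
    label = "Klaassen 2000", tiers = c("low", "high"), target = "sre",
    classify = function(d) {
      need_cols(d, "amc", "klaassen")
      ifelse(d$amc < 0.1, "high", "low")
    },
    restrict = function(d)
      d$new_diagnosis == 0 & d$hsct_history == 0 & d$inpatient_onset == 0,
    restrict_desc = "exclude newly diagnosed, prior HSCT, inpatient onset")

  reg$baorto <- list(
    label = "Baorto 2001", tiers = c("low", "high"), target = "bacteremia",
    classify = function(d) {
      need_cols(d, "amc", "baorto")
      ifelse(d$amc < 0.155, "high", "low")
    },
    restrict = function(d) d$age_years >= 1 & d$hsct_history == 0,
    restrict_desc = "exclude age < 1 y, prior HSCT")

  reg$madsen <- list(
    label = "Madsen 2002", tiers = c("low", "high"), target = "bacteremia",
    classify = function(d) {
      need_cols(d, c("amc", "temperature_at_presentation"), "madsen")
      ifelse(d$temperature_at_presentation >= 39.5 & d$amc <= 0.01,
             "high", "low")
    },
    restrict = function(d) d$hsct_history == 0 & d$inpatient_onset == 0,
    restrict_desc = "exclude prior HSCT, inpatient onset")

  reg$rondinelli <- list(
    label = "Rondinelli 2006", tiers = c("low", "intermediate", "high"),
    target = "sre",
    classify = function(d) {
      need_cols(d, c("age_years", "cvad", "clinical_site_infection",
                     "temperature_at_presentation", "hemoglobin", "urti"),
                "rondinelli")
      s <- 1 * (d$age_years <= 5) + 2 * d$cvad +
        4.5 * d$clinical_site_infection +
        1 * (d$temperature_at_presentation > 38.5) +
        1 * (d$hemoglobin <= 70) + 2.5 * d$urti
      ifelse(s >= 9, "high", ifelse(s >= 5.5, "intermediate", "low"))
    },
    restrict = function(d)
      d$hsct_history == 0 & d$inpatient_onset == 0 &
        d$prior_fn_count == 0 & d$episode_index == 1,
    restrict_desc = "exclude prior HSCT, inpatient onset, non-first FN episodes")

  reg$spog_ae <- list(
    label = "SPOG-AE (Ammann) 2010", tiers = c("low", "high"), target = "sre",
    classify = function(d) {
      need_cols(d, c("chemo_intensity_above_ALL_maintenance", "hemoglobin",
                     "leucocyte_count", "platelet_count"), "spog_ae")
      s <- 4 * d$chemo_intensity_above_ALL_maintenance +
        5 * (d$hemoglobin >= 90) + 3 * (d$leucocyte_count < 0.3) +
        3 * (d$platelet_count < 50)
      ifelse(s >= 9, "high", "low")
    },
    restrict = function(d) d$inpatient_onset == 0,
    restrict_desc = "exclude inpatient-onset FN")

  reg$hakim <- list(
    label = "Hakim 2010", tiers = c("low", "high"), target = "sre",
    classify = function(d) {
      need_cols(d, c("malignancy_type", "severely_reduced_general_condition",
                     "temperature_at_presentation", "anc"), "hakim")
      s <- 20 * (d$malignancy_type == "AML") +
        7 * (d$malignancy_type %in% c("ALL", "Hodgkin", "NHL")) +
        14 * d$severely_reduced_general_condition +
        11 * (d$temperature_at_presentation >= 39) + 10 * (d$anc < 0.1)
      ifelse(s >= 24, "high", "low")
    },
    restrict = function(d) d$hsct_history == 0 & d$inpatient_onset == 0,
    restrict_desc = "exclude prior HSCT, inpatient onset")

  reg$suttitossatam <- list(
    label = "Suttitossatam 2020", tiers = c("low", "high"), target = "smc",
    classify = function(d) {
      need_cols(d, "age_years", "suttitossatam")
      ifelse(d$age_years >= 10, "high", "low")
    },
    restrict = function(d) d$age_years >= 1,
    restrict_desc = "exclude age < 1 y")

  aus_classify <- function(d) {
    need_cols(d, c("chemo_intensity_above_ALL_maintenance", "leucocyte_count",
                   "platelet_count"), "aus")
    s <- d$chemo_intensity_above_ALL_maintenance +
      (d$leucocyte_count < 0.3) + (d$platelet_count < 50)
    ifelse(s >= 1, "high", "low")
  }
  aus_restrict <- function(d) d$hsct_history == 0
  for (v in c("aus_lbi", "aus_bacteremia", "aus_icu")) {
    reg[[v]] <- list(
      label = paste0("AUS (Haeusler) 2020, ",
                     switch(v, aus_lbi = "likely bacterial infection",
                            aus_bacteremia = "bacteremia",
                            aus_icu = "ICU admission")),
      tiers = c("low", "high"),
      target = switch(v, aus_lbi = "sre", aus_bacteremia = "bacteremia",
                      aus_icu = "smc"),
      classify = aus_classify,
      restrict = aus_restrict,
      restrict_desc = "exclude recent HSCT")
  }
  reg
}

get_cdr <- function(cdr_id) {
  reg <- published_cdrs()
  if (!cdr_id %in% names(reg))
    stop("unknown CDR id '", cdr_id, "'; known: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[cdr_id]]
}

#' Classify episodes with a published CDR
#'
#' @param cdr_id rule id (see [published_cdrs()]).
#' @param data episode data frame.
#' @return factor of risk tiers (`low` < `intermediate` < `high` for
#'   three-tier rules, `low` < `high` otherwise).
#' @export
classify_cdr <- function(cdr_id, data) {
  rule <- get_cdr(cdr_id)
  factor(rule$classify(data), levels = rule$tiers, ordered = TRUE)
}

#' Restricted validation dataset for a published CDR
#'
#' Applies the schema-representable part of a rule's original in-/exclusion
#' criteria. The number of dropped episodes is attached as attribute
#' `dropped`.
#'
#' @inheritParams classify_cdr
#' @return filtered episode data frame (attribute `dropped` = rows removed).
#' @export
restrict_dataset <- function(cdr_id, data) {
  rule <- get_cdr(cdr_id)
  keep <- rule$restrict(data)
  out <- data[keep, , drop = FALSE]
  attr(out, "dropped") <- sum(!keep)
  attr(out, "filter") <- rule$restrict_desc
  out
}

#' Externally validate a published CDR on an episode table
#'
#' Classifies the full table (VD) and the restricted one (rVD) with the
#' binarized rule (low vs intermediate/high) against the rule's target
#' outcome, computes performance reports with an AUROC over all risk tiers,
#' and assesses reproducibility against the publication's
#' derivation-dataset counts when supplied.
#'
#' @param cdr_id rule id.
#' @param data episode data frame (validation dataset).
#' @param dd_counts optional list/`fn_confusion` with the published tp, tn,
#'   fp, fn counts.
#' @param outcome optional override of the rule's default target outcome.
#' @return object of class `fn_validation`: `vd` and `rvd` performance
#'   reports, `dropped` episode count, `verdict`, ids.
#' @export
validate_cdr <- function(cdr_id, data, dd_counts = NULL, outcome = NULL) {
  rule <- get_cdr(cdr_id)
  outcome <- outcome %||% rule$target
  eval_on <- function(d) {
    tier <- classify_cdr(cdr_id, d)
    y <- d[[outcome]]
    perf <- performance(confusion_matrix(tier != "low", y),
                        auroc = auroc(as.integer(tier), y))
    perf
  }
  vd <- eval_on(data)
  rdata <- restrict_dataset(cdr_id, data)
  rvd <- if (nrow(rdata) && length(unique(rdata[[outcome]])) == 2)
    eval_on(rdata) else NULL
  verdict <- reproducibility_verdict(
    dd_counts, as.list(vd$counts),
    if (!is.null(rvd)) as.list(rvd$counts) else NULL)
  structure(list(cdr_id = cdr_id, label = rule$label, outcome = outcome,
                 vd = vd, rvd = rvd, dropped = attr(rdata, "dropped"),
                 verdict = verdict),
            class = "fn_validation")
}

#' @export
print.fn_validation <- function(x, ...) {
  cat(sprintf("External validation of %s (target outcome: %s)\n",
              x$label, x$outcome))
  cat("Validation dataset (VD):\n"); print(x$vd)
  if (!is.null(x$rvd)) {
    cat(sprintf("Restricted validation dataset (rVD, %d dropped):\n",
                x$dropped))
    print(x$rvd)
  } else {
    cat(sprintf("rVD not evaluable (%d dropped)\n", x$dropped))
  }
  cat("Reproducibility vs derivation dataset:", x$verdict$overall, "\n")
  invisible(x)
}

#' Registry metadata from the shipped YAML document
#'
#' Reads the registry mapping table (`inst/extdata/published_cdrs.yaml`):
#' per rule, the default target-outcome mapping and the rVD filter
#' description. The tier logic itself lives in [published_cdrs()]; this
#' document is the declarative record of the mapping decisions.
#'
#' @param path YAML path (default: the file shipped with the package).
#' @return data frame with columns `id`, `label`, `target_outcome`,
#'   `rvd_filter`.
#' @export
cdr_registry_metadata <- function(path = system.file("extdata",
                                                     "published_cdrs.yaml",
                                                     package = "fncdr")) {
  raw <- yaml::read_yaml(path)
  do.call(rbind, lapply(raw$rules, function(r)
    data.frame(id = r$id, label = r$label,
               target_outcome = r$target_outcome,
               rvd_filter = r$rvd_filter, stringsAsFactors = FALSE)))
}

#' Read published derivation-dataset counts
#'
#' CSV with columns `cdr_id, tp, tn, fp, fn`; missing rules are reported as
#' not assessable by [validate_cdr()].
#'
#' @param path CSV path.
#' @return named list of count lists keyed by cdr_id.
#' @export
read_dd_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cdr_id", "tp", "tn", "fp", "fn")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("dd_counts file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(d)))
    out[[d$cdr_id[i]]] <- list(tp = d$tp[i], tn = d$tn[i], fp = d$fp[i],
                               fn = d$fn[i])
  out
}
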