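# Orchestration of the two study workflows: derive-and-cross-validate the
# new CDRs, and externally validate the published ones. All artifacts embed
# the seed and a hash of the run configuration so a rerun with the same
# configuration reproduces byte-identical CSV/JSON payloads.

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                           digits = NA)), tf)
  unname(tools::md5sum(tf))
}

score_to_list <- function(score) {
  list(outcome = score$outcome,
       weights = lapply(score$weights, as.list),
       offsets = as.list(score$offsets),
       threshold = score$threshold,
       max_score = score$max_score,
       provenance = lapply(score$provenance, function(x)
         if (length(x) > 1) as.list(x) else x))
}

write_json_artifact <- function(x, path, meta) {
  jsonlite::write_json(c(meta, x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Run the CDR derivation workflow
#'
#' For each requested outcome: univariable screen, interaction screen
#' against the randomized fever limit (logged), forward selection, weight
#' derivation, threshold calibration, full-data per-threshold performance
#' table, and replicated internal cross-validation. A stage error aborts
#' that outcome with a structured log entry; other outcomes proceed. When
#' `outdir` is given, artifacts are written per outcome:
#' `score_<outcome>.json`, `performance_<outcome>.csv`,
#' `cv_<outcome>.json`, `screen_<outcome>.csv`, `steps_<outcome>.csv`, and
#' `episodes.csv` when the cohort was simulated here.
#'
#' @param input episode data frame, or an `fn_cohort_config` to simulate
#'   from.
#' @param outcomes outcomes to derive rules for.
#' @param candidates characteristics entering the univariable screen.
#' @param outdir optional output directory.
#' @param seed integer seed for guard/CV fold draws.
#' @param cv_reps,cv_folds internal cross-validation size.
#' @param cv_engine per-fold refit engine (see [internal_cv()]).
#' @param guard_reps,guard_folds overfitting-guard CV size.
#' @param alpha_screen,alpha_entry,alpha_interaction significance levels.
#' @param min_sensitivity threshold calibration target.
#' @param grouping random-intercept structure.
#' @return list with `cdrs` (per-outcome `fn_cdr` or error entry),
#'   `interactions` (per-outcome screen log), `errors`, `seed`,
#'   `config_hash`.
#' @export
run_derivation <- function(input, outcomes = c("bacteremia", "smc", "sre"),
                           candidates = fn_characteristics(),
                           outdir = NULL, seed = 1L,
                           cv_reps = 100L, cv_folds = 10L,
                           cv_engine = "glm",
                           guard_reps = 100L, guard_folds = 10L,
                           alpha_screen = 0.05, alpha_entry = 0.05,
                           alpha_interaction = 0.01,
                           min_sensitivity = 0.90,
                           grouping = "center_patient") {
  simulated <- inherits(input, "fn_cohort_config")
  data <- if (simulated) generate_cohort(input) else input
  validate_episodes(data)
  params <- list(outcomes = outcomes, candidates = candidates, seed = seed,
                 cv_reps = cv_reps,
                 cv_folds = cv_folds, cv_engine = cv_engine,
                 guard_reps = guard_reps, guard_folds = guard_folds,
                 alpha_screen = alpha_screen, alpha_entry = alpha_entry,
                 alpha_interaction = alpha_interaction,
                 min_sensitivity = min_sensitivity, grouping = grouping,
                 simulated = simulated,
                 cohort_seed = if (simulated) input$seed else NA)
  hash <- config_hash(params)
  meta <- list(config_hash = hash, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (simulated) write_episodes(data, file.path(outdir, "episodes.csv"))
  }
  cdrs <- list(); interactions <- list(); errors <- list()
  for (oc in outcomes) {
    res <- tryCatch({
      cdr <- derive_cdr(data, oc, candidates = candidates,
                        alpha_screen = alpha_screen,
                        alpha_entry = alpha_entry, guard_reps = guard_reps,
                        guard_folds = guard_folds,
                        min_sensitivity = min_sensitivity,
                        cv_reps = cv_reps, cv_folds = cv_folds,
                        cv_engine = cv_engine, seed = seed,
                        grouping = grouping)
      ix <- lapply(cdr$screen$significant, function(ch) {
        p <- tryCatch(
          interaction_screen(data, oc, ch, alpha_interaction, grouping),
          error = function(e) list(p_value = NA_real_, significant = NA))
        data.frame(characteristic = ch, p_value = p$p_value,
                   significant = p$significant, stringsAsFactors = FALSE)
      })
      ix <- if (length(ix)) do.call(rbind, ix) else
        data.frame(characteristic = character(), p_value = numeric(),
                   significant = logical())
      list(cdr = cdr, interactions = ix)
    }, error = identity)
    if (inherits(res, "condition")) {
      errors[[oc]] <- conditionMessage(res)
      next
    }
    cdrs[[oc]] <- res$cdr
    interactions[[oc]] <- res$interactions
    if (!is.null(outdir)) {
      cdr <- res$cdr
      write_json_artifact(score_to_list(cdr$score),
                          file.path(outdir, paste0("score_", oc, ".json")),
                          meta)
      pt <- cbind(data.frame(config_hash = hash, seed = seed),
                  cdr$performance_table)
      utils::write.csv(pt, file.path(outdir, paste0("performance_", oc, ".csv")),
                       row.names = FALSE)
      utils::write.csv(cbind(data.frame(config_hash = hash, seed = seed),
                             cdr$screen$results),
                       file.path(outdir, paste0("screen_", oc, ".csv")),
                       row.names = FALSE)
      utils::write.csv(cbind(data.frame(config_hash = hash, seed = seed),
                             cdr$selection$step_log),
                       file.path(outdir, paste0("steps_", oc, ".csv")),
                       row.names = FALSE)
      if (!is.null(cdr$cv))
        write_json_artifact(
          list(outcome = oc, reps = cdr$cv$reps, folds = cdr$cv$folds,
               dropped = cdr$cv$dropped,
               summary = cdr$cv$summary),
          file.path(outdir, paste0("cv_", oc, ".json")), meta)
    }
  }
  list(cdrs = cdrs, interactions = interactions, errors = errors,
       seed = seed, config_hash = hash, data = data)
}

#' Run the external-validation workflow
#'
#' Validates the selected published rules on the episode table (VD) and
#' their restricted datasets (rVD), produces the per-rule performance table
#' and reproducibility classification counts, and optionally writes
#' `external_validation.csv` plus a sensitivity-versus-specificity scatter
#' with CI bars under `figures/`.
#'
#' @param data episode data frame.
#' @param cdr_ids rules to validate (default: all eleven).
#' @param dd_counts named list of published derivation-dataset counts, or a
#'   CSV path for [read_dd_counts()]; rules without counts are reported as
#'   not assessable.
#' @param outdir optional output directory.
#' @return list with `table` (one row per rule), `reports` (per-rule
#'   `fn_validation`), `verdict_counts`.
#' @export
run_external_validation <- function(data, cdr_ids = names(published_cdrs()),
                                    dd_counts = NULL, outdir = NULL) {
  validate_episodes(data)
  if (is.character(dd_counts) && length(dd_counts) == 1)
    dd_counts <- read_dd_counts(dd_counts)
  reports <- list()
  rows <- list()
  for (id in cdr_ids) {
    rep <- validate_cdr(id, data, dd_counts[[id]])
    reports[[id]] <- rep
    g <- function(p, metric, col) {
      if (is.null(p)) return(NA_real_)
      m <- p$metrics
      m[[col]][m$metric == metric]
    }
    rows[[id]] <- data.frame(
      cdr_id = id, label = rep$label, outcome = rep$outcome,
      n_vd = sum(rep$vd$counts), n_rvd = if (is.null(rep$rvd)) NA_integer_
        else sum(rep$rvd$counts),
      dropped = rep$dropped,
      vd_sensitivity = g(rep$vd, "sensitivity", "estimate"),
      vd_sens_lower = g(rep$vd, "sensitivity", "lower"),
      vd_sens_upper = g(rep$vd, "sensitivity", "upper"),
      vd_specificity = g(rep$vd, "specificity", "estimate"),
      vd_spec_lower = g(rep$vd, "specificity", "lower"),
      vd_spec_upper = g(rep$vd, "specificity", "upper"),
      vd_auroc = rep$vd$auroc,
      rvd_sensitivity = g(rep$rvd, "sensitivity", "estimate"),
      rvd_specificity = g(rep$rvd, "specificity", "estimate"),
      reproducibility = rep$verdict$overall,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame()
  verdict_counts <- if (nrow(tab)) table(tab$reproducibility) else table(character())
  if (!is.null(outdir) && nrow(tab)) {
    dir.create(file.path(outdir, "figures"), recursive = TRUE,
               showWarnings = FALSE)
    utils::write.csv(tab, file.path(outdir, "external_validation.csv"),
                     row.names = FALSE)
    grDevices::pdf(file.path(outdir, "figures", "external_validation.pdf"),
                   width = 7, height = 6)
    plot_validation_summary(tab)
    grDevices::dev.off()
  }
  list(table = tab, reports = reports, verdict_counts = verdict_counts)
}

#' Sensitivity-versus-specificity summary plot
#'
#' Scatter of the validated rules' sensitivity against specificity on the
#' validation dataset, with 95% CI bars.
#'
#' @param tab table from [run_external_validation()].
#' @export
plot_validation_summary <- function(tab) {
  graphics::plot(tab$vd_specificity, tab$vd_sensitivity, pch = 16,
                 xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "specificity (%)", ylab = "sensitivity (%)",
                 main = "External validation of published CDRs")
  graphics::segments(tab$vd_spec_lower, tab$vd_sensitivity,
                     tab$vd_spec_upper, tab$vd_sensitivity, col = "grey50")
  graphics::segments(tab$vd_specificity, tab$vd_sens_lower,
                     tab$vd_specificity, tab$vd_sens_upper, col = "grey50")
  graphics::text(tab$vd_specificity, tab$vd_sensitivity, labels = tab$cdr_id,
                 pos = 3, cex = 0.7)
  invisible(tab)
}
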