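#' Specification of one end-to-end analysis
#'
#' Bundles the analysis identifier (candidate-covariate set), cohort mode,
#' outcomes, tree-search control, and propensity settings.
#'
#' @param analysis `"primary"`, `"sens1"`, `"sens2"`, or `"sens3"` (the last
#'   runs on the imputed full cohort).
#' @param outcomes Subset of the four composite outcomes.
#' @param control A [trl_control()].
#' @param folds,learners,num_trees,outcome_learner Propensity / outcome-model
#'   settings, as in [trl()].
#' @param seed Integer seed.
#' @return A list of class `analysis_spec`.
#' @export
analysis_spec <- function(analysis = c("primary", "sens1", "sens2", "sens3"),
                          outcomes = c("strength", "dexterity", "pain",
                                       "qol"),
                          control = trl_control(), folds = 10L,
                          learners = c("mean", "glm", "tree", "forest"),
                          num_trees = 300L,
                          outcome_learner = c("forest", "linear"),
                          seed = 1L) {
  analysis <- match.arg(analysis)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  outcome_learner <- match.arg(outcome_learner)
  structure(list(analysis = analysis,
                 cohort_mode = if (analysis == "sens3") "imputed" else
                   "complete_case",
                 outcomes = outcomes, control = control, folds = folds,
                 learners = learners, num_trees = num_trees,
                 outcome_learner = outcome_learner, seed = seed),
            class = "analysis_spec")
}

#' Run a full multi-outcome analysis
#'
#' Orchestrates one analysis end to end: optional imputation (`sens3` on a
#' cohort with missing data), restriction to the common complete-case
#' cohort, one shared propensity fit with balance diagnostics, then per
#' outcome the composite construction, outcome model, AIPW pseudo-outcomes,
#' tree search, and Table-style rule rendering with both single-action
#' comparator values.
#'
#' @param cohort A `cohort`.
#' @param spec An [analysis_spec()].
#' @return An object of class `trl_report`: per-outcome fitted `trl`
#'   objects, the shared balance report, the cohort summary, and provenance
#'   bookkeeping.
#' @export
run_analysis <- function(cohort, spec = analysis_spec()) {
  imputed <- FALSE
  if (spec$cohort_mode == "imputed" &&
      anyNA(as.data.frame(cohort)[, -1])) {
    cohort <- rf_impute(cohort, impute_control(seed = spec$seed))
    imputed <- TRUE
  }
  required <- unique(c(candidate_covariates("primary"),
                       propensity_covariates(), outcome_fields("all")))
  cc <- complete_cases(cohort, required)
  removed <- attr(cc, "removed_per_field")

  A <- factor(cc$treatment, levels = treatment_levels())
  Xp <- as.data.frame(cc)[, propensity_covariates(), drop = FALSE]
  pm <- fit_propensity(Xp, A, folds = spec$folds, seed = spec$seed,
                       learners = spec$learners,
                       num_trees = spec$num_trees)
  bal <- balance_report(Xp, A, pm$fitted)

  fits <- lapply(spec$outcomes, function(o) {
    trl(cc, outcome = o, analysis = spec$analysis, control = spec$control,
        propensity = pm, outcome_learner = spec$outcome_learner,
        num_trees = spec$num_trees, seed = spec$seed)
  })
  names(fits) <- spec$outcomes

  structure(list(
    analysis = spec$analysis, spec = spec, fits = fits, balance = bal,
    propensity = pm, summary = summarize_cohort(cc), n = nrow(cc),
    imputed = imputed, removed_per_field = removed, seed = spec$seed),
    class = "trl_report")
}

#' @export
print.trl_report <- function(x, ...) {
  cat(sprintf("T-RL analysis report: %s analysis, n = %d%s\n", x$analysis,
              x$n, if (x$imputed) " (imputed cohort)" else ""))
  for (o in names(x$fits)) {
    f <- x$fits[[o]]
    cat(sprintf("  %-9s %s\n", paste0(o, ":"), render_rule(f$rule)))
    cat(sprintf("            value %.4f (treat-all revision %.4f, replantation %.4f)\n",
                f$value, f$comparators[["revision_amputation"]],
                f$comparators[["replantation"]]))
  }
  cat(sprintf("  max weighted ASMD: %.3f (%d covariate terms flagged)\n",
              max(x$balance$table$asmd_weighted), length(x$balance$flags)))
  invisible(x)
}

#' Export a report as machine-readable JSON
#'
#' @param report A `trl_report`.
#' @param path Output path; `NULL` returns the JSON string.
#' @export
report_json <- function(report, path = NULL) {
  obj <- list(
    analysis = report$analysis,
    n = report$n,
    imputed = report$imputed,
    seed = report$seed,
    rules = lapply(report$fits, function(f) list(
      outcome = f$outcome,
      rule_text = render_rule(f$rule),
      rule = jsonlite::fromJSON(rule_json(f$rule), simplifyVector = FALSE),
      value = f$value,
      comparators = as.list(f$comparators),
      n = f$n)),
    balance = list(table = report$balance$table,
                   flags = report$balance$flags),
    propensity_weights = as.list(report$propensity$weights),
    removed_per_field = as.list(report$removed_per_field))
  out <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA, pretty = TRUE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' Export a report as human-readable Markdown
#'
#' @param report A `trl_report`.
#' @param path Output path; `NULL` returns the text.
#' @export
report_markdown <- function(report, path = NULL) {
  lines <- c(
    sprintf("# T-RL decision-rule report (%s analysis)", report$analysis),
    "",
    sprintf("Cohort: n = %d%s.", report$n,
            if (report$imputed) ", imputed full cohort" else
              ", complete cases"),
    "",
    "## Estimated decision rules",
    "",
    "| Optimization goal | Estimated decision rule | Value | Treat-all revision | Treat-all replantation |",
    "|---|---|---|---|---|")
  for (o in names(report$fits)) {
    f <- report$fits[[o]]
    lines <- c(lines, sprintf(
      "| %s | %s | %.4f | %.4f | %.4f |", o, render_rule(f$rule), f$value,
      f$comparators[["revision_amputation"]],
      f$comparators[["replantation"]]))
  }
  bal <- report$balance
  lines <- c(lines, "",
             "## Covariate balance",
             "",
             sprintf("Maximum weighted absolute standardized mean difference: %.3f.",
                     max(bal$table$asmd_weighted)),
             if (length(bal$flags)) {
               sprintf("Covariates above the %.2g threshold: %s.",
                       bal$threshold, paste(bal$flags, collapse = ", "))
             } else {
               sprintf("All covariates at or below the %.2g threshold.",
                       bal$threshold)
             })
  out <- paste(lines, collapse = "\n")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}
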