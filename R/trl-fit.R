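#' Estimate an optimal individualized treatment rule by T-RL
#'
#' The main fitting function.  Given a cohort, it (1) restricts to records
#' complete for the tailoring covariates, propensity confounders and the raw
#' measures of the requested outcome, (2) builds the composite outcome,
#' (3) fits the stacked-ensemble propensity score with balance diagnostics,
#' (4) fits per-arm outcome models and forms doubly robust AIPW
#' pseudo-outcomes, and (5) grows a shallow decision tree over the analysis's
#' candidate tailoring covariates by recursive partitioning on the estimated
#' counterfactual mean outcome.
#'
#' @param cohort A `cohort` data frame.
#' @param outcome `"strength"`, `"dexterity"`, `"pain"` or `"qol"`.
#' @param analysis Candidate-covariate set: `"primary"`, `"sens1"` (ordinal
#'   injury group only), `"sens2"` (primary without age), `"sens3"` (primary
#'   candidates; pass an imputed full cohort).
#' @param control A [trl_control()].
#' @param propensity Optionally a prefitted `propensity_model` whose fitted
#'   probabilities align with the complete-case cohort (used by
#'   [run_analysis()] to share one propensity fit across outcomes).
#' @param outcome_learner `"forest"` or `"linear"` conditional-mean learner.
#' @param folds Stacking folds for the propensity ensemble.
#' @param num_trees Trees for forest learners.
#' @param learners Propensity base-learner roster.
#' @param pain_violation `"truncate"` or `"drop"` handling of records whose
#'   healthy hand hurts more than the injured hand (pain outcome only).
#' @param seed Integer seed.
#' @return An object of class `trl` with the grown rule, its estimated
#'   value, both single-action comparator values, the propensity model and
#'   balance report, the AIPW matrix, and the analysis cohort.
#' @seealso [grow_tree()], [aipw_scores()], [fit_propensity()]
#' @export
trl <- function(cohort, outcome = c("strength", "dexterity", "pain", "qol"),
                analysis = c("primary", "sens1", "sens2", "sens3"),
                control = trl_control(), propensity = NULL,
                outcome_learner = c("forest", "linear"), folds = 10L,
                num_trees = 300L,
                learners = c("mean", "glm", "tree", "forest"),
                pain_violation = c("truncate", "drop"), seed = 1L) {
  outcome <- match.arg(outcome)
  analysis <- match.arg(analysis)
  outcome_learner <- match.arg(outcome_learner)
  pain_violation <- match.arg(pain_violation)
  cl <- match.call()

  required <- unique(c(candidate_covariates("primary"),
                       propensity_covariates(), outcome_fields(outcome)))
  cc <- complete_cases(cohort, required)

  co <- if (outcome == "pain") {
    pain_score(cc, violation = pain_violation)
  } else {
    composite_outcome(cc, outcome)
  }
  cc <- cc[match(co$patient_id, cc$patient_id), , drop = FALSE]
  Y <- co$scores
  A <- factor(cc$treatment, levels = treatment_levels())

  Xp <- as.data.frame(cc)[, propensity_covariates(), drop = FALSE]
  pm <- propensity
  if (is.null(pm)) {
    pm <- fit_propensity(Xp, A, folds = folds, seed = seed,
                         learners = learners, num_trees = num_trees)
  }
  pi_hat <- pm$fitted
  if (length(pi_hat) != nrow(cc)) {
    stop("trl: prefitted propensity does not align with the analysis cohort",
         call. = FALSE)
  }
  bal <- balance_report(Xp, A, pi_hat)

  om <- fit_outcome_model(Xp, A, Y, learner = outcome_learner,
                          num_trees = num_trees, seed = seed)
  psi <- aipw_scores(Y, A, pi_hat, om, Xp)

  cands <- candidate_covariates(analysis)
  Xt <- as.data.frame(cc)
  if (analysis == "sens1") Xt$injury_group <- derive_injury_group(cc)
  Xt <- Xt[, cands, drop = FALSE]
  ctrl <- control
  ctrl$candidates <- cands
  rule <- grow_tree(psi, Xt, ctrl)

  value <- rule_value(psi, predict_rule(rule, Xt))
  comparators <- c(revision_amputation = mean(psi[, 1L]),
                   replantation = mean(psi[, 2L]))

  structure(list(
    outcome = outcome, analysis = analysis, rule = rule, value = value,
    comparators = comparators, propensity = pm, balance = bal,
    outcome_model = om, psi = psi, composite = co, cohort = cc,
    tailoring = Xt, control = ctrl, seed = seed, n = nrow(cc), call = cl),
    class = "trl")
}

#' @export
print.trl <- function(x, ...) {
  cat(sprintf("T-RL individualized treatment rule (%s outcome, %s analysis)\n",
              x$outcome, x$analysis))
  cat(sprintf("  n = %d complete cases\n", x$n))
  cat(sprintf("  rule:  %s\n", render_rule(x$rule)))
  cat(sprintf("  estimated counterfactual mean under rule: %.4f\n", x$value))
  cat(sprintf("  treat-all comparators: revision %.4f, replantation %.4f\n",
              x$comparators[["revision_amputation"]],
              x$comparators[["replantation"]]))
  invisible(x)
}

#' @export
summary.trl <- function(object, ...) {
  structure(list(fit = object), class = "summary.trl")
}

#' @export
print.summary.trl <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nDecision tree:\n")
  print(f$rule)
  cat("\nPropensity ensemble:\n")
  print(f$propensity)
  cat("\nCovariate balance:\n")
  print(f$balance)
  invisible(x)
}

#' Assign treatments to new patients under a fitted rule
#'
#' @param object A fitted `trl` object.
#' @param newdata Data frame with the rule's tailoring covariates; defaults
#'   to the analysis cohort.
#' @param ... Unused.
#' @return Factor of assigned arms.
#' @export
predict.trl <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$tailoring else {
    nd <- as.data.frame(newdata)
    if (object$analysis == "sens1" && !("injury_group" %in% names(nd))) {
      nd$injury_group <- derive_injury_group(nd)
    }
    nd
  }
  predict_rule(object$rule, X)
}

#' Propensity overlap and covariate-balance plot
#'
#' Two base-graphics panels: per-arm histograms of the estimated propensity
#' score (overlap), and a dot chart of weighted vs unadjusted absolute
#' standardized mean differences with the 0.1 adequacy threshold.
#'
#' @param x A fitted `trl` object.
#' @param ... Unused.
#' @export
plot.trl <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  pi_hat <- x$propensity$fitted
  repl <- x$cohort$treatment == "replantation"
  brk <- seq(0, 1, by = 0.05)
  h1 <- graphics::hist(pi_hat[!repl], breaks = brk, plot = FALSE)
  h2 <- graphics::hist(pi_hat[repl], breaks = brk, plot = FALSE)
  ylim <- c(0, max(h1$counts, h2$counts))
  graphics::plot(h1, col = grDevices::adjustcolor("firebrick", 0.5),
                 xlim = c(0, 1), ylim = ylim, main = "Propensity overlap",
                 xlab = "P(replantation | X)")
  graphics::plot(h2, col = grDevices::adjustcolor("steelblue", 0.5),
                 add = TRUE)
  graphics::legend("topleft", fill = c("firebrick", "steelblue"),
                   legend = c("revision amputation", "replantation"),
                   bty = "n", cex = 0.8)
  tab <- x$balance$table[order(x$balance$table$asmd_unadjusted), ]
  graphics::dotchart(tab$asmd_unadjusted, labels = tab$covariate,
                     pch = 1, cex = 0.55, xlim = c(0, max(
                       tab$asmd_unadjusted, tab$asmd_weighted, 0.12)),
                     main = "Covariate balance", xlab = "absolute SMD")
  graphics::points(tab$asmd_weighted, seq_len(nrow(tab)), pch = 19,
                   col = "steelblue", cex = 0.7)
  graphics::abline(v = x$balance$threshold, lty = 2)
  graphics::legend("bottomright", pch = c(1, 19),
                   col = c("black", "steelblue"),
                   legend = c("unadjusted", "IPW-weighted"), bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Residual-style diagnostics for a fitted rule
#'
#' Per-patient regret estimates: the difference between the pointwise-best
#' pseudo-outcome and the pseudo-outcome under the rule's assignment.  Zero
#' for patients whose assignment matches their pointwise argmax.
#'
#' @param object A fitted `trl` object.
#' @param ... Unused.
#' @return Numeric vector (non-negative).
#' @export
residuals.trl <- function(object, ...) {
  assign_idx <- match(as.character(predict(object)), treatment_levels())
  apply(object$psi, 1, max) -
    object$psi[cbind(seq_len(nrow(object$psi)), assign_idx)]
}
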