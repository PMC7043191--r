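# Ground-truth machinery for the synthetic generator: potential-outcome
# composites and the brute-force Monte-Carlo oracle used by rule-recovery
# experiments.

#' Composite potential outcomes from a generated cohort
#'
#' Uses the `potential_outcomes` attribute attached by [generate_cohort()] to
#' compute, for every patient, the composite outcome that would be observed
#' under each arm.  Standardization constants come from the observed cohort
#' (the same constants [composite_outcome()] uses), so the potential
#' outcomes are on exactly the analysis scale; being shared by all rules,
#' rule values stay comparable.
#'
#' @param cohort A synthetic `cohort` carrying potential outcomes.
#' @param outcome Composite name.
#' @return n x 2 matrix (columns `revision_amputation`, `replantation`).
#' @export
po_composite <- function(cohort, outcome = c("strength", "dexterity",
                                             "pain", "qol")) {
  outcome <- match.arg(outcome)
  po <- attr(cohort, "potential_outcomes")
  if (is.null(po)) {
    stop("po_composite: cohort has no potential_outcomes attribute",
         call. = FALSE)
  }
  obs_z <- function(d_obs, d_rev, d_repl) {
    mu <- mean(d_obs)
    s <- stats::sd(d_obs)
    cbind((d_rev - mu) / s, (d_repl - mu) / s)
  }
  if (outcome == "strength") {
    pairs <- list(c("grip_injured_kg", "grip_healthy_kg"),
                  c("pinch_lateral_inj_kg", "pinch_lateral_hea_kg"),
                  c("pinch_2pt_inj_kg", "pinch_2pt_hea_kg"),
                  c("pinch_3pt_inj_kg", "pinch_3pt_hea_kg"))
    z <- lapply(pairs, function(p) {
      obs_z(cohort[[p[1]]] - cohort[[p[2]]],
            po[[p[1]]][, 1] - cohort[[p[2]]],
            po[[p[1]]][, 2] - cohort[[p[2]]])
    })
    out <- Reduce(`+`, z) / length(z)
  } else if (outcome == "dexterity") {
    out <- obs_z(cohort$nine_hole_hea_s - cohort$nine_hole_inj_s,
                 cohort$nine_hole_hea_s - po$nine_hole_inj_s[, 1],
                 cohort$nine_hole_hea_s - po$nine_hole_inj_s[, 2])
  } else if (outcome == "pain") {
    out <- obs_z(pmin(0, cohort$pain_hea_0_100 - cohort$pain_inj_0_100),
                 pmin(0, cohort$pain_hea_0_100 - po$pain_inj_0_100[, 1]),
                 pmin(0, cohort$pain_hea_0_100 - po$pain_inj_0_100[, 2]))
  } else {
    zm <- obs_z(cohort$mhq_0_100, po$mhq_0_100[, 1], po$mhq_0_100[, 2])
    zd <- obs_z(100 - cohort$dash_0_100, 100 - po$dash_0_100[, 1],
                100 - po$dash_0_100[, 2])
    out <- (zm + zd) / 2
  }
  colnames(out) <- treatment_levels()
  out
}

po_value <- function(po, assignments) {
  a <- match(as.character(assignments), treatment_levels())
  mean(po[cbind(seq_len(nrow(po)), a)])
}

#' Brute-force oracle for the configured optimal rule
#'
#' Simulates `grid_n` patients with both potential outcomes, evaluates the
#' configured true rule's counterfactual mean, and verifies that neither a
#' single-action rule, nor any single split on a candidate covariate (with
#' per-side best actions taken from the potential-outcome means), nor a
#' random sample of comparator rules beats it by more than two Monte-Carlo
#' standard errors.  A configuration whose declared rule is beaten raises an
#' error.
#'
#' @param config A `generator_config`.
#' @param outcome Composite name.
#' @param grid_n Monte-Carlo sample size (default 100000).
#' @param seed Integer seed.
#' @param n_comparators Random depth-<=2 comparator rules to test
#'   (default 50).
#' @param rule Rule to check; defaults to the configured true rule.  Passing
#'   a different rule lets the oracle evaluate (and possibly reject) an
#'   alternative claim against the same generating mechanism.
#' @return List of class `oracle_rule`: the declared `rule`, its Monte-Carlo
#'   `value`, `single_action_values`, the best comparator margin, and the
#'   Monte-Carlo standard error.
#' @export
oracle_optimal_rule <- function(config, outcome, grid_n = 100000L, seed = 1L,
                                n_comparators = 50L,
                                rule = config$true_rules[[outcome]]) {
  cohort <- generate_cohort(config, n = grid_n, seed = seed)
  po <- po_composite(cohort, outcome)
  X <- as.data.frame(cohort)[, candidate_covariates("primary")]
  v_rule_i <- po[cbind(seq_len(grid_n),
                       match(as.character(predict_rule(rule, X)),
                             treatment_levels()))]
  v_rule <- mean(v_rule_i)
  check <- function(po_comp_i, label) {
    d <- v_rule_i - po_comp_i
    se <- stats::sd(d) / sqrt(grid_n)
    margin <- mean(d)
    if (margin < -2 * se) {
      stop(sprintf(
        "oracle_optimal_rule: declared %s rule beaten by %s (margin %.4g, MC se %.4g)",
        outcome, label, margin, se), call. = FALSE)
    }
    margin
  }
  single <- colMeans(po)
  for (arm in treatment_levels()) {
    check(po[, arm], sprintf("treat-all %s", arm))
  }
  # every single split on a candidate covariate, sides assigned their best arm
  worst_margin <- Inf
  for (v in names(X)) {
    x <- X[[v]]
    xv <- if (is.logical(x)) as.numeric(x) else
      if (is.factor(x)) as.numeric(x) else x
    thr <- unique(stats::quantile(xv, seq(0.1, 0.9, by = 0.1),
                                  names = FALSE))
    for (t in thr) {
      left <- xv <= t
      if (!any(left) || all(left)) next
      comp_i <- numeric(grid_n)
      for (side in list(left, !left)) {
        best_arm <- which.max(colMeans(po[side, , drop = FALSE]))
        comp_i[side] <- po[side, best_arm]
      }
      worst_margin <- min(worst_margin, check(comp_i, sprintf(
        "split %s <= %.3g", v, t)))
    }
  }
  # random comparator rules
  set.seed(derive_seed(seed, "oracle"))
  for (r in seq_len(n_comparators)) {
    comp <- random_rule(X, max_depth = sample(1:2, 1))
    comp_i <- po[cbind(seq_len(grid_n),
                       match(as.character(predict_rule(comp, X)),
                             treatment_levels()))]
    worst_margin <- min(worst_margin, check(comp_i, "random comparator"))
  }
  structure(list(rule = rule, outcome = outcome, value = v_rule,
                 single_action_values = single,
                 min_margin = worst_margin,
                 mc_se = stats::sd(v_rule_i) / sqrt(grid_n),
                 grid_n = grid_n),
            class = "oracle_rule")
}

#' @export
print.oracle_rule <- function(x, ...) {
  cat(sprintf("<oracle_rule> %s outcome, MC n = %d\n", x$outcome, x$grid_n))
  cat(sprintf("  declared rule value: %.4f (MC se %.4g)\n", x$value,
              x$mc_se))
  cat(sprintf("  treat-all values: revision %.4f, replantation %.4f\n",
              x$single_action_values[["revision_amputation"]],
              x$single_action_values[["replantation"]]))
  cat(sprintf("  minimum margin over comparators: %.4g\n", x$min_margin))
  invisible(x)
}

# Random depth-<=2 rule over the covariates of X; used as oracle comparators.
random_rule <- function(X, max_depth = 2L) {
  rand_leaf <- function() rule_leaf(sample(treatment_levels(), 1))
  rand_split <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.3) return(rand_leaf())
    v <- sample(names(X), 1)
    x <- X[[v]]
    if (is.factor(x) && nlevels(x) > 2L) {
      lv <- sample(levels(x), sample(seq_len(nlevels(x) - 1L), 1))
      rule_split(v, levels = lv, left = rand_split(depth + 1L),
                 right = rand_split(depth + 1L))
    } else {
      xv <- if (is.logical(x)) as.numeric(x) else
        if (is.factor(x)) as.numeric(x) else x
      t <- stats::quantile(xv, stats::runif(1, 0.1, 0.9), names = FALSE)
      rule_split(v, threshold = t, left = rand_split(depth + 1L),
                 right = rand_split(depth + 1L))
    }
  }
  node <- rand_split(0L)
  if (node$type == "leaf") {
    # guarantee at least one split so comparators differ from single actions
    v <- sample(names(X), 1)
    x <- X[[v]]
    xv <- if (is.logical(x)) as.numeric(x) else
      if (is.factor(x)) as.numeric(x) else x
    node <- rule_split(v, threshold = stats::median(xv) + 0.25,
                       left = rand_leaf(), right = rand_leaf())
  }
  node
}
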