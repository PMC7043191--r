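#' Decision-rule node constructors
#'
#' A decision rule is a shallow binary tree.  Internal nodes split on one
#' tailoring covariate: numeric/ordinal covariates by `value <= threshold`
#' (logicals are coded 0/1, so `threshold = 0.5` splits FALSE/TRUE), nominal
#' covariates by membership in a level subset (`levels`); the left child
#' receives records satisfying the condition.  Leaves carry the assigned
#' treatment arm.
#'
#' @param action For `rule_leaf`, one of `"revision_amputation"`,
#'   `"replantation"`.
#' @param n,value Optional leaf bookkeeping (node size and estimated
#'   counterfactual-mean purity).
#' @param covariate Covariate name for an internal node.
#' @param threshold Numeric threshold (`<=` goes left).
#' @param levels Character level subset (membership goes left); exactly one
#'   of `threshold`/`levels` must be given.
#' @param left,right Child nodes.
#' @return A list of class `trl_node`.
#' @export
rule_leaf <- function(action, n = NA_integer_, value = NA_real_) {
  stopifnot(action %in% treatment_levels())
  structure(list(type = "leaf", action = action, n = n, value = value),
            class = "trl_node")
}

#' @rdname rule_leaf
#' @export
rule_split <- function(covariate, threshold = NULL, levels = NULL,
                       left, right) {
  if (is.null(threshold) == is.null(levels)) {
    stop("rule_split: give exactly one of threshold or levels", call. = FALSE)
  }
  structure(list(type = "split", covariate = covariate,
                 kind = if (is.null(levels)) "numeric" else "nominal",
                 threshold = threshold, levels = levels,
                 left = left, right = right),
            class = "trl_node")
}

rule_depth <- function(node) {
  if (node$type == "leaf") 0L else
    1L + max(rule_depth(node$left), rule_depth(node$right))
}

rule_covariates <- function(node) {
  if (node$type == "leaf") character(0) else
    unique(c(node$covariate, rule_covariates(node$left),
             rule_covariates(node$right)))
}

split_goes_left <- function(node, X) {
  x <- X[[node$covariate]]
  if (is.null(x)) {
    stop(sprintf("predict_rule: covariate '%s' not in data", node$covariate),
         call. = FALSE)
  }
  if (node$kind == "numeric") {
    xv <- if (is.logical(x)) as.numeric(x) else
      if (is.factor(x)) as.numeric(x) else x
    if (anyNA(xv)) {
      stop(sprintf("predict_rule: missing '%s' at record(s) %s",
                   node$covariate,
                   paste(utils::head(which(is.na(xv)), 5), collapse = ", ")),
           call. = FALSE)
    }
    xv <= node$threshold
  } else {
    if (anyNA(x)) {
      stop(sprintf("predict_rule: missing '%s' at record(s) %s",
                   node$covariate,
                   paste(utils::head(which(is.na(x)), 5), collapse = ", ")),
           call. = FALSE)
    }
    as.character(x) %in% node$levels
  }
}

#' Apply a decision rule to a covariate table
#'
#' Routes every record through the tree; total and deterministic.
#'
#' @param rule A `trl_node`.
#' @param X Data frame containing every covariate the rule references.
#' @return Factor of assigned arms with levels
#'   `c("revision_amputation", "replantation")`.
#' @export
predict_rule <- function(rule, X) {
  out <- character(nrow(X))
  recurse <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$type == "leaf") {
      out[idx] <<- node$action
      return()
    }
    goes_left <- split_goes_left(node, X[idx, , drop = FALSE])
    recurse(node$left, idx[goes_left])
    recurse(node$right, idx[!goes_left])
  }
  recurse(rule, seq_len(nrow(X)))
  factor(out, levels = treatment_levels())
}

#' Control parameters for the T-RL tree search
#'
#' @param max_depth Maximum tree depth (default 2).
#' @param lambda Minimum improvement in the purity measure needed for a new
#'   split, as a fraction (default 0.05, i.e. 5\%).  A split is accepted when
#'   `purity(split) - purity(no split) >= lambda * |purity(no split)|`; when
#'   the no-split purity is within `abs_fallback_frac` of zero relative to the
#'   spread of the pseudo-outcomes, the criterion falls back to
#'   `lambda * sd(psi in node)` so a near-zero purity on standardized outcomes
#'   cannot make every split admissible.
#' @param min_node_size Minimum records per leaf (default 20).
#' @param abs_fallback_frac Relative-purity floor triggering the absolute
#'   fallback (default 0.1).
#' @param candidates Candidate tailoring covariates; default all columns of
#'   the covariate table handed to [grow_tree()].
#' @return A list of class `trl_control`.
#' @export
trl_control <- function(max_depth = 2L, lambda = 0.05, min_node_size = 20L,
                        abs_fallback_frac = 0.1, candidates = NULL) {
  stopifnot(max_depth >= 1L, lambda > 0, lambda < 1, min_node_size >= 1L)
  structure(list(max_depth = as.integer(max_depth), lambda = lambda,
                 min_node_size = as.integer(min_node_size),
                 abs_fallback_frac = abs_fallback_frac,
                 candidates = candidates),
            class = "trl_control")
}

#' Best single treatment arm for a node
#'
#' The arm maximizing the mean AIPW pseudo-outcome over the node; ties go to
#' replantation.
#'
#' @param psi n x 2 matrix of AIPW pseudo-outcomes with columns
#'   `revision_amputation`, `replantation`.
#' @param subset Integer indices of the node's records.
#' @return List with `action` and `purity` (the mean pseudo-outcome).
#' @export
best_single_action <- function(psi, subset = seq_len(nrow(psi))) {
  if (length(subset) == 0L) stop("best_single_action: empty subset",
                                 call. = FALSE)
  m_rev <- mean(psi[subset, 1L])
  m_repl <- mean(psi[subset, 2L])
  if (m_repl >= m_rev) list(action = "replantation", purity = m_repl)
  else list(action = "revision_amputation", purity = m_rev)
}

#' Enumerate admissible candidate splits in a node
#'
#' Numeric and ordinal covariates: thresholds at midpoints of consecutive
#' distinct observed values within the node; logicals: the single 0/1 split;
#' nominal factors: all nonempty proper subsets of observed levels up to
#' complementation.  Splits leaving a child smaller than `min_node_size` are
#' excluded.
#'
#' @param X Covariate table.
#' @param covariates Candidate covariate names.
#' @param subset Node record indices.
#' @param min_node_size Minimum child size.
#' @return List of split descriptors
#'   (`covariate`, `kind`, `threshold`/`levels`).
#' @export
enumerate_candidate_splits <- function(X, covariates, subset,
                                       min_node_size = 20L) {
  out <- list()
  for (v in covariates) {
    x <- X[[v]][subset]
    if (is.factor(x) && nlevels(droplevels(x)) > 2L) {
      lev <- levels(droplevels(x))
      # subsets of lev[-length(lev)] are unique up to complementation
      base <- lev[-length(lev)]
      for (k in seq_len(length(base))) {
        for (cmb in utils::combn(base, k, simplify = FALSE)) {
          nl <- sum(as.character(x) %in% cmb)
          if (nl >= min_node_size && length(x) - nl >= min_node_size) {
            out[[length(out) + 1L]] <- list(covariate = v, kind = "nominal",
                                            threshold = NULL, levels = cmb)
          }
        }
      }
    } else {
      xv <- if (is.logical(x)) as.numeric(x) else
        if (is.factor(x)) as.numeric(droplevels(x)) else x
      ux <- sort(unique(xv))
      if (length(ux) < 2L) next
      thr <- (ux[-1] + ux[-length(ux)]) / 2
      for (t in thr) {
        nl <- sum(xv <= t)
        if (nl >= min_node_size && length(xv) - nl >= min_node_size) {
          lv <- if (is.factor(x)) levels(droplevels(x))[1L] else NULL
          if (is.factor(x)) {
            out[[length(out) + 1L]] <- list(covariate = v, kind = "nominal",
                                            threshold = NULL, levels = lv)
          } else {
            out[[length(out) + 1L]] <- list(covariate = v, kind = "numeric",
                                            threshold = t, levels = NULL)
          }
        }
      }
    }
  }
  out
}

# Weighted purity of a split: (n_L * purity_L + n_R * purity_R) / n with each
# child's purity from its best single action.  Vectorized over all admissible
# thresholds of one numeric covariate via cumulative sums in sorted order.
score_numeric_splits <- function(psi, xv, subset, min_node_size) {
  ord <- order(xv[subset])
  idx <- subset[ord]
  xs <- xv[idx]
  n <- length(idx)
  cs1 <- cumsum(psi[idx, 1L])
  cs2 <- cumsum(psi[idx, 2L])
  tot1 <- cs1[n]; tot2 <- cs2[n]
  # boundary after position k is admissible iff xs[k] < xs[k+1]
  k <- seq_len(n - 1L)
  ok <- xs[k] < xs[k + 1L] & k >= min_node_size & (n - k) >= min_node_size
  if (!any(ok)) return(NULL)
  k <- k[ok]
  purity <- (pmax(cs1[k], cs2[k]) + pmax(tot1 - cs1[k], tot2 - cs2[k])) / n
  list(thresholds = (xs[k] + xs[k + 1L]) / 2, purity = purity)
}

#' Best admissible split of a node
#'
#' Maximizes the weighted counterfactual-mean purity over every admissible
#' candidate split; returns the split only when its improvement over the
#' no-split purity passes the minimum-improvement rule of [trl_control()].
#' Ties are broken deterministically: earlier covariate in the candidate
#' list, then smaller threshold.
#'
#' @param psi AIPW pseudo-outcome matrix.
#' @param X Covariate table.
#' @param subset Node record indices.
#' @param control A `trl_control`.
#' @return A list (`covariate`, `kind`, `threshold`/`levels`, `purity`,
#'   `improvement`) or `NULL` when no split qualifies.
#' @export
best_split <- function(psi, X, subset, control = trl_control()) {
  candidates <- control$candidates %||% names(X)
  n <- length(subset)
  if (n < 2L * control$min_node_size) return(NULL)
  base <- best_single_action(psi, subset)
  best <- NULL
  consider <- function(desc, purity) {
    if (is.null(best) || purity > best$purity) {
      best <<- c(desc, list(purity = purity))
    }
  }
  for (v in candidates) {
    x <- X[[v]][subset]
    if (is.factor(x) && nlevels(droplevels(x)) > 2L) {
      splits <- enumerate_candidate_splits(X, v, subset,
                                           control$min_node_size)
      for (s in splits) {
        left <- subset[as.character(X[[v]][subset]) %in% s$levels]
        right <- setdiff(subset, left)
        p <- (length(left) * best_single_action(psi, left)$purity +
              length(right) * best_single_action(psi, right)$purity) / n
        consider(s, p)
      }
    } else {
      two_level_factor <- is.factor(x)
      xv <- if (is.logical(x)) as.numeric(x) else
        if (two_level_factor) as.numeric(droplevels(x)) else x
      full <- rep(NA_real_, nrow(X))
      full[subset] <- xv
      sc <- score_numeric_splits(psi, full, subset, control$min_node_size)
      if (is.null(sc)) next
      for (j in seq_along(sc$thresholds)) {
        desc <- if (two_level_factor) {
          list(covariate = v, kind = "nominal", threshold = NULL,
               levels = levels(droplevels(x))[1L])
        } else {
          list(covariate = v, kind = "numeric",
               threshold = sc$thresholds[j], levels = NULL)
        }
        consider(desc, sc$purity[j])
      }
    }
  }
  if (is.null(best)) return(NULL)
  improvement <- best$purity - base$purity
  sd_node <- stats::sd(as.vector(psi[subset, ]))
  threshold_gain <- if (abs(base$purity) < control$abs_fallback_frac * sd_node)
    control$lambda * sd_node else control$lambda * abs(base$purity)
  if (improvement < threshold_gain) return(NULL)
  c(best, list(improvement = improvement, no_split_purity = base$purity,
               required_gain = threshold_gain))
}

#' Grow a T-RL decision tree
#'
#' Recursive partitioning over the candidate tailoring covariates, splitting
#' on the expected counterfactual mean outcome (AIPW purity) until the
#' maximum depth, minimum node size, or minimum-improvement rule stops it.
#' Leaves are labeled with their best single action.  A root with no
#' qualifying split yields a depth-0 single-action rule.
#'
#' @param psi n x 2 AIPW pseudo-outcome matrix (columns
#'   `revision_amputation`, `replantation`).
#' @param X Covariate table aligned with `psi`.
#' @param control A `trl_control`; `control$candidates` restricts the
#'   tailoring covariates (default: all columns of `X`).
#' @return A `trl_node` tree.
#' @export
grow_tree <- function(psi, X, control = trl_control()) {
  stopifnot(nrow(psi) == nrow(X), ncol(psi) == 2L)
  grow <- function(subset, depth) {
    base <- best_single_action(psi, subset)
    if (depth >= control$max_depth) {
      return(rule_leaf(base$action, n = length(subset), value = base$purity))
    }
    sp <- best_split(psi, X, subset, control)
    if (is.null(sp)) {
      return(rule_leaf(base$action, n = length(subset), value = base$purity))
    }
    node <- if (sp$kind == "numeric") {
      goes_left <- {
        x <- X[[sp$covariate]][subset]
        xv <- if (is.logical(x)) as.numeric(x) else x
        xv <= sp$threshold
      }
      rule_split(sp$covariate, threshold = sp$threshold,
                 left = grow(subset[goes_left], depth + 1L),
                 right = grow(subset[!goes_left], depth + 1L))
    } else {
      goes_left <- as.character(X[[sp$covariate]][subset]) %in% sp$levels
      rule_split(sp$covariate, levels = sp$levels,
                 left = grow(subset[goes_left], depth + 1L),
                 right = grow(subset[!goes_left], depth + 1L))
    }
    node
  }
  grow(seq_len(nrow(psi)), 0L)
}

pretty_arm <- function(a) {
  c(revision_amputation = "revision amputation",
    replantation = "replantation")[[a]]
}

fmt_num <- function(x) trimws(formatC(x, format = "fg", digits = 3))

describe_condition <- function(covariate, side, threshold = NULL,
                               levels = NULL) {
  mech_pretty <- c(clean_cut = "clean-cut", avulsion = "avulsion",
                   crush = "crush")
  if (!is.null(levels)) {
    if (covariate == "mechanism") {
      lv <- mech_pretty[levels]
      if (side == "right") lv <- mech_pretty[setdiff(names(mech_pretty),
                                                     levels)]
      return(sprintf("had a %s injury", paste(lv, collapse = " or ")))
    }
    if (covariate == "amputation_level") {
      lv <- if (side == "left") levels else
        setdiff(c("distal", "proximal"), levels)
      return(sprintf("had an amputation %s to the PIP or IP joint",
                     paste(lv, collapse = " or ")))
    }
    lv <- if (side == "left") levels else sprintf("not %s", levels)
    return(sprintf("has %s = %s", covariate, paste(lv, collapse = " or ")))
  }
  k <- floor(threshold)
  switch(covariate,
    age = if (side == "left") sprintf("is aged ≤%s y", fmt_num(threshold))
          else sprintf("is aged >%s y", fmt_num(threshold)),
    n_fingers_amputated = if (side == "left") {
      if (k == 1) "had 1 finger amputated"
      else sprintf("had ≤%d fingers amputated", k)
    } else sprintf("had ≥%d fingers amputated", k + 1),
    injury_group = if (side == "left")
      sprintf("is in injury group ≤%d", k)
      else sprintf("is in injury group ≥%d", k + 1),
    thumb_amputated = if (side == "left") "did not have a thumb amputated"
      else "had a thumb amputated",
    dominant_hand_injured = if (side == "left")
      "did not injure the dominant hand" else "injured the dominant hand",
    bilateral = if (side == "left") "did not have a bilateral injury"
      else "had a bilateral injury",
    work_related = if (side == "left") "did not have a work-related injury"
      else "had a work-related injury",
    if (side == "left") sprintf("has %s ≤ %s", covariate,
                                fmt_num(threshold))
    else sprintf("has %s > %s", covariate, fmt_num(threshold))
  )
}

rule_paths <- function(node, conds = character(0)) {
  if (node$type == "leaf") {
    return(list(list(action = node$action, conditions = conds)))
  }
  lc <- describe_condition(node$covariate, "left", node$threshold,
                           node$levels)
  rc <- describe_condition(node$covariate, "right", node$threshold,
                           node$levels)
  c(rule_paths(node$left, c(conds, lc)), rule_paths(node$right, c(conds, rc)))
}

#' Render a decision rule as an English sentence
#'
#' Depth-0 rules render as "Treat all patients with <arm>"; deeper rules as
#' "If the patient <conditions>, treat with <arm>; otherwise, <other arm>".
#'
#' @param rule A `trl_node`.
#' @return Character scalar.
#' @export
render_rule <- function(rule) {
  paths <- rule_paths(rule)
  actions <- vapply(paths, `[[`, "", "action")
  if (length(unique(actions)) == 1L) {
    return(sprintf("Treat all patients with %s", pretty_arm(actions[1L])))
  }
  n_rev <- sum(actions == "revision_amputation")
  n_repl <- sum(actions == "replantation")
  if_action <- if (n_rev <= n_repl) "revision_amputation" else "replantation"
  other <- setdiff(treatment_levels(), if_action)
  clauses <- vapply(paths[actions == if_action], function(p) {
    paste(p$conditions, collapse = " and ")
  }, "")
  sprintf("If the patient %s, treat with %s; otherwise, %s",
          paste(clauses, collapse = ", or "), pretty_arm(if_action),
          pretty_arm(other))
}

#' @export
print.trl_node <- function(x, ...) {
  cat(render_rule(x), "\n")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s<leaf> %s%s\n", pad, node$action,
                  if (is.na(node$n)) "" else
                    sprintf(" (n = %d, purity = %.4f)", node$n, node$value)))
    } else {
      lab <- if (node$kind == "numeric") {
        sprintf("%s <= %s", node$covariate, fmt_num(node$threshold))
      } else {
        sprintf("%s in {%s}", node$covariate,
                paste(node$levels, collapse = ", "))
      }
      cat(sprintf("%s<split> %s\n", pad, lab))
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  show(x, 0L)
  invisible(x)
}

#' Serialize / deserialize a decision rule as JSON
#'
#' @param rule A `trl_node`.
#' @param path Optional output path.
#' @export
rule_json <- function(rule, path = NULL) {
  strip <- function(node) {
    if (node$type == "leaf") {
      list(type = "leaf", action = node$action, n = node$n,
           value = node$value)
    } else {
      list(type = "split", covariate = node$covariate, kind = node$kind,
           threshold = node$threshold, levels = as.list(node$levels),
           left = strip(node$left), right = strip(node$right))
    }
  }
  out <- jsonlite::toJSON(strip(rule), auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' @rdname rule_json
#' @param json JSON string or path produced by `rule_json`.
#' @export
rule_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  build <- function(node) {
    if (node$type == "leaf") {
      rule_leaf(node$action, n = node$n %||% NA_integer_,
                value = node$value %||% NA_real_)
    } else {
      rule_split(node$covariate, threshold = node$threshold,
                 levels = if (length(node$levels)) unlist(node$levels),
                 left = build(node$left), right = build(node$right))
    }
  }
  build(obj)
}
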