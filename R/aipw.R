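#' Fit per-arm conditional-mean outcome models
#'
#' Fits a regression of the composite outcome on covariates separately within
#' each treatment arm (default learner: random forest; alternative:
#' main-effects linear model), providing finite predictions for every record
#' under both arms -- the outcome-model half of the AIPW construction.
#'
#' @param X Covariate data frame (no missing values).
#' @param A Treatment vector.
#' @param Y Numeric outcome (composite score), aligned with `X`.
#' @param learner `"forest"` or `"linear"`.
#' @param min_arm_n Minimum records per arm (default 20).
#' @param num_trees Trees for the forest learner.
#' @param seed Integer seed.
#' @return An object of class `outcome_model` with a
#'   `predict(object, newdata, arm)` method.
#' @export
fit_outcome_model <- function(X, A, Y, learner = c("forest", "linear"),
                              min_arm_n = 20L, num_trees = 300L, seed = 1L) {
  learner <- match.arg(learner)
  A <- factor(as.character(A), levels = treatment_levels())
  stopifnot(nrow(X) == length(A), length(Y) == length(A))
  if (anyNA(X) || anyNA(Y)) {
    stop("fit_outcome_model: missing values in X or Y", call. = FALSE)
  }
  arm_n <- table(A)
  if (any(arm_n < min_arm_n)) {
    stop(sprintf(
      "fit_outcome_model: arm below %d observations (%s); consider a pooled model",
      min_arm_n, paste(names(arm_n)[arm_n < min_arm_n], collapse = ", ")),
      call. = FALSE)
  }
  Xd <- one_hot(X)
  fits <- lapply(treatment_levels(), function(arm) {
    idx <- which(A == arm)
    ord <- idx[canonical_order(Xd[idx, , drop = FALSE])]
    d <- cbind(Xd[ord, , drop = FALSE], .y = Y[ord])
    if (learner == "forest") {
      ranger::ranger(.y ~ ., data = d, num.trees = num_trees, seed = seed,
                     num.threads = 1)
    } else {
      stats::lm(.y ~ ., data = d)
    }
  })
  names(fits) <- treatment_levels()
  structure(list(fits = fits, learner = learner, seed = seed,
                 feature_list = names(X), design_cols = names(Xd)),
            class = "outcome_model")
}

#' @export
predict.outcome_model <- function(object, newdata,
                                  arm = treatment_levels(), ...) {
  arm <- match.arg(arm)
  fit <- object$fits[[arm]]
  newdata <- align_design(one_hot(newdata), object$design_cols)
  out <- if (object$learner == "forest") {
    as.numeric(stats::predict(fit, data = newdata,
                              num.threads = 1)$predictions)
  } else {
    # rank-deficient designs (aliased indicator columns) predict fine with
    # the aliased coefficients dropped; silence the advisory warning
    suppressWarnings(as.numeric(stats::predict(fit, newdata = newdata)))
  }
  if (any(!is.finite(out))) {
    stop("predict.outcome_model: non-finite prediction", call. = FALSE)
  }
  out
}

#' Doubly robust AIPW pseudo-outcomes
#'
#' For each patient i and arm a computes
#' `psi[i, a] = 1\{A_i = a\} / pi_a(X_i) * (Y_i - m(X_i, a)) + m(X_i, a)`,
#' where `pi_repl = pi` and `pi_rev = 1 - pi`.  The column means of `psi` are
#' consistent for the counterfactual means E\[Y(a)\] when either the
#' propensity or the outcome model is correctly specified.
#'
#' @param Y Numeric outcome vector.
#' @param A Treatment vector aligned with `Y`.
#' @param pi P(A = replantation | X), within truncation bounds.
#' @param model An `outcome_model`, or a precomputed n x 2 matrix of
#'   conditional-mean predictions (columns `revision_amputation`,
#'   `replantation`).
#' @param X Covariate table, required when `model` is an `outcome_model`.
#' @return n x 2 matrix of class `aipw_scores`; the IPW-residual and model
#'   components are kept in attributes `ipw_term` and `model_term`.
#' @export
aipw_scores <- function(Y, A, pi, model, X = NULL) {
  A <- factor(as.character(A), levels = treatment_levels())
  n <- length(Y)
  stopifnot(length(A) == n, length(pi) == n)
  if (any(pi <= 0 | pi >= 1)) {
    stop("aipw_scores: propensity outside (0, 1)", call. = FALSE)
  }
  m <- if (is.matrix(model)) {
    model
  } else {
    if (is.null(X)) stop("aipw_scores: X required with an outcome_model",
                         call. = FALSE)
    cbind(revision_amputation = predict(model, X, "revision_amputation"),
          replantation = predict(model, X, "replantation"))
  }
  pi_mat <- cbind(revision_amputation = 1 - pi, replantation = pi)
  ind <- cbind(revision_amputation = as.numeric(A == "revision_amputation"),
               replantation = as.numeric(A == "replantation"))
  ipw_term <- ind / pi_mat * (Y - m)
  psi <- ipw_term + m
  if (any(!is.finite(psi))) {
    stop("aipw_scores: non-finite pseudo-outcome at record(s) ",
         paste(utils::head(which(rowSums(!is.finite(psi)) > 0), 5),
               collapse = ", "), call. = FALSE)
  }
  structure(psi, class = c("aipw_scores", class(psi)),
            ipw_term = ipw_term, model_term = m)
}

#' Estimated value of a treatment assignment
#'
#' Mean AIPW pseudo-outcome under the given per-patient assignments over a
#' subset: the estimated counterfactual mean outcome if the subset followed
#' those assignments.
#'
#' @param psi AIPW pseudo-outcome matrix.
#' @param assignments Treatment vector (one arm per patient).
#' @param subset Indices to average over (default all).
#' @return Numeric scalar.
#' @export
rule_value <- function(psi, assignments, subset = seq_len(nrow(psi))) {
  if (length(subset) == 0L) stop("rule_value: empty subset", call. = FALSE)
  a <- match(as.character(assignments), treatment_levels())
  mean(psi[cbind(subset, a[subset])])
}
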