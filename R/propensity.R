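#' Fit the stacked-ensemble propensity score
#'
#' Estimates P(A = replantation | X) with a small fixed roster of base
#' learners -- intercept-only, main-effects logistic regression, a single
#' classification tree, and a probability random forest -- combined by
#' cross-validated stacking: out-of-fold predictions from arm-stratified
#' folds are weighted to minimize the cross-validated Brier score, with
#' weights solved by non-negative least squares and normalized onto the
#' simplex.  Ensemble predictions are the weight-averaged full-data learner
#' probabilities, truncated to `bounds`.
#'
#' Rows are processed in a canonical covariate order internally, so the
#' fitted probabilities do not depend on the caller's row order.
#'
#' @param X Covariate data frame (factors/logicals/numerics; no missing
#'   values).
#' @param A Treatment factor/character with both arms present.
#' @param folds Number of stacking folds (default 10), stratified by arm.
#' @param seed Integer seed (random-forest learner).
#' @param bounds Truncation bounds for the predicted probabilities.
#' @param learners Subset of `c("mean", "glm", "tree", "forest")`.
#' @param num_trees Trees for the forest learner.
#' @return An object of class `propensity_model` with elements `weights`,
#'   `fitted` (training-data probabilities), `cv_brier` (per learner and
#'   ensemble), `learners`, `bounds`, `feature_list`.
#' @export
fit_propensity <- function(X, A, folds = 10L, seed = 1L,
                           bounds = c(0.01, 0.99),
                           learners = c("mean", "glm", "tree", "forest"),
                           num_trees = 300L) {
  A <- factor(as.character(A), levels = treatment_levels())
  stopifnot(nrow(X) == length(A), !anyNA(A))
  if (anyNA(X)) stop("fit_propensity: X contains missing values",
                     call. = FALSE)
  arm_n <- table(A)
  if (any(arm_n == 0L)) stop("fit_propensity: both arms must be present",
                             call. = FALSE)
  if (min(arm_n) < 2L) stop("fit_propensity: an arm has < 2 records",
                            call. = FALSE)
  folds <- as.integer(folds)
  if (folds < 2L) stop("fit_propensity: folds must be >= 2", call. = FALSE)
  if (min(arm_n) < folds) {
    folds <- as.integer(min(arm_n))
    warning(sprintf("fit_propensity: folds reduced to %d (smallest arm)",
                    folds), call. = FALSE)
  }

  Xd <- one_hot(X)
  ord <- canonical_order(Xd, A)
  Xo <- Xd[ord, , drop = FALSE]
  yo <- as.integer(A[ord] == "replantation")
  dat <- cbind(Xo, .y = factor(ifelse(yo == 1L, "replantation",
                                      "revision_amputation"),
                               levels = treatment_levels()))
  n <- nrow(dat)

  # deterministic arm-stratified round-robin folds in canonical order
  fold_id <- integer(n)
  for (arm in 0:1) {
    idx <- which(yo == arm)
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }

  defs <- list(
    mean = list(
      fit = function(d) mean(d$.y == "replantation"),
      predict = function(fit, d) rep(fit, nrow(d))),
    glm = list(
      fit = function(d) suppressWarnings(
        stats::glm(.y ~ ., data = d, family = stats::binomial())),
      predict = function(fit, d) suppressWarnings(
        as.numeric(stats::predict(fit, newdata = d, type = "response")))),
    tree = list(
      fit = function(d) rpart::rpart(
        .y ~ ., data = d, method = "class",
        control = rpart::rpart.control(cp = 0.01, minbucket = 10,
                                       xval = 0)),
      predict = function(fit, d)
        as.numeric(stats::predict(fit, newdata = d,
                                  type = "prob")[, "replantation"])),
    forest = list(
      # generous terminal nodes: probability forests with deep leaves give
      # poorly calibrated probabilities, which inverse weighting amplifies
      fit = function(d) ranger::ranger(
        .y ~ ., data = d, probability = TRUE, num.trees = num_trees,
        min.node.size = max(10, floor(nrow(d) / 50)),
        seed = seed, num.threads = 1,
        respect.unordered.factors = "order"),
      predict = function(fit, d)
        as.numeric(stats::predict(fit, data = d,
                                  num.threads = 1)$predictions[,
                                                    "replantation"]))
  )[learners]

  safe_fit <- function(def, d) tryCatch(def$fit(d), error = function(e) NULL)

  cv_pred <- matrix(NA_real_, n, length(defs),
                    dimnames = list(NULL, names(defs)))
  for (k in seq_len(folds)) {
    train <- dat[fold_id != k, , drop = FALSE]
    test <- dat[fold_id == k, , drop = FALSE]
    if (length(unique(train$.y)) < 2L) {
      stop("fit_propensity: a training fold contains a single arm",
           call. = FALSE)
    }
    for (l in names(defs)) {
      fit <- safe_fit(defs[[l]], train)
      if (!is.null(fit)) {
        cv_pred[fold_id == k, l] <- tryCatch(
          defs[[l]]$predict(fit, test), error = function(e) NA_real_)
      }
    }
  }
  ok <- colSums(is.na(cv_pred)) == 0L
  if (any(!ok)) {
    warning("fit_propensity: dropping degenerate learner(s): ",
            paste(names(defs)[!ok], collapse = ", "), call. = FALSE)
    defs <- defs[ok]
    cv_pred <- cv_pred[, ok, drop = FALSE]
    if (ncol(cv_pred) == 0L) {
      stop("fit_propensity: no learner survived cross-validation",
           call. = FALSE)
    }
  }

  # stacking weights: NNLS on the CV predictions, normalized to the simplex
  w <- pracma::lsqnonneg(cv_pred, yo)$x
  if (sum(w) <= 0) w <- rep(1, ncol(cv_pred))
  w <- w / sum(w)
  names(w) <- colnames(cv_pred)

  cv_brier <- c(colMeans((cv_pred - yo)^2),
                ensemble = mean((as.numeric(cv_pred %*% w) - yo)^2))

  fits <- lapply(names(defs), function(l) safe_fit(defs[[l]], dat))
  names(fits) <- names(defs)
  keep <- !vapply(fits, is.null, TRUE)
  fits <- fits[keep]
  w <- w[keep]; w <- w / sum(w)
  defs <- defs[keep]

  full_pred <- vapply(names(defs), function(l) defs[[l]]$predict(fits[[l]],
                                                                 dat),
                      numeric(n))
  p_canon <- clip(as.numeric(full_pred %*% w), bounds[1], bounds[2])
  fitted <- numeric(n)
  fitted[ord] <- p_canon

  structure(list(
    weights = w, learners = fits, learner_defs = defs,
    cv_brier = cv_brier, folds = folds, bounds = bounds,
    feature_list = names(X), design_cols = names(Xd), fitted = fitted,
    seed = seed),
    class = "propensity_model")
}

#' @export
predict.propensity_model <- function(object, newdata, ...) {
  newdata <- align_design(one_hot(newdata), object$design_cols)
  preds <- vapply(names(object$learners), function(l) {
    object$learner_defs[[l]]$predict(object$learners[[l]], newdata)
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) preds <- matrix(preds, nrow = 1L)
  clip(as.numeric(preds %*% object$weights), object$bounds[1],
       object$bounds[2])
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model> stacked ensemble, P(A = replantation | X)\n")
  cat(sprintf("  folds: %d, truncation: [%.3g, %.3g]\n", x$folds,
              x$bounds[1], x$bounds[2]))
  cat("  weights:\n")
  for (l in names(x$weights)) {
    cat(sprintf("    %-8s %.4f  (CV Brier %.4f)\n", l, x$weights[[l]],
                x$cv_brier[[l]]))
  }
  cat(sprintf("  ensemble CV Brier: %.4f\n", x$cv_brier[["ensemble"]]))
  invisible(x)
}

expand_balance_columns <- function(X) {
  cols <- list()
  for (v in names(X)) {
    x <- X[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- list(values = x, binary = FALSE)
    } else if (is.logical(x)) {
      cols[[v]] <- list(values = as.numeric(x), binary = TRUE)
    } else {
      xf <- factor(x)
      for (lv in levels(xf)) {
        cols[[paste(v, lv, sep = ":")]] <-
          list(values = as.numeric(xf == lv), binary = TRUE)
      }
    }
  }
  cols
}

#' Covariate balance diagnostics
#'
#' Absolute standardized mean differences (ASMD) per covariate, unadjusted
#' and weighted by the inverse propensity of the received treatment.
#' Continuous covariates are standardized by the pooled (unadjusted) SD,
#' binary covariates and factor-level indicators by `sqrt(p*(1-p))` at the
#' pooled proportion.  Covariates with weighted ASMD above 0.1 (the
#' conventional adequacy threshold) are flagged; per-arm propensity
#' quantiles summarize overlap.
#'
#' @param X Covariate data frame.
#' @param A Treatment vector.
#' @param propensity Vector of P(A = replantation | X), strictly in (0, 1).
#' @param threshold Flagging threshold (default 0.1).
#' @return An object of class `balance_report`: data frame `table`
#'   (`covariate`, `asmd_unadjusted`, `asmd_weighted`, `flagged`), `overlap`
#'   quantiles, `flags`.
#' @export
balance_report <- function(X, A, propensity, threshold = 0.1) {
  A <- factor(as.character(A), levels = treatment_levels())
  if (any(propensity <= 0 | propensity >= 1)) {
    stop("balance_report: propensity must lie strictly in (0, 1)",
         call. = FALSE)
  }
  repl <- A == "replantation"
  w <- ifelse(repl, 1 / propensity, 1 / (1 - propensity))
  cols <- expand_balance_columns(X)
  rows <- list()
  wmean <- function(x, idx) sum(w[idx] * x[idx]) / sum(w[idx])
  for (nm in names(cols)) {
    x <- cols[[nm]]$values
    if (cols[[nm]]$binary) {
      pbar <- (mean(x[repl]) + mean(x[!repl])) / 2
      denom <- sqrt(pbar * (1 - pbar))
    } else {
      denom <- sqrt((stats::var(x[repl]) + stats::var(x[!repl])) / 2)
    }
    if (!is.finite(denom) || denom == 0) {
      warning(sprintf("balance_report: '%s' has zero pooled SD; skipped", nm),
              call. = FALSE)
      next
    }
    rows[[nm]] <- data.frame(
      covariate = nm,
      asmd_unadjusted = abs(mean(x[repl]) - mean(x[!repl])) / denom,
      asmd_weighted = abs(wmean(x, repl) - wmean(x, !repl)) / denom)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$flagged <- tab$asmd_weighted > threshold
  qs <- c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)
  structure(list(
    table = tab,
    overlap = rbind(
      revision_amputation = stats::quantile(propensity[!repl], qs),
      replantation = stats::quantile(propensity[repl], qs)),
    threshold = threshold,
    flags = tab$covariate[tab$flagged]),
    class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> %d covariate terms, threshold %.2g\n",
              nrow(x$table), x$threshold))
  cat(sprintf("  max weighted ASMD: %.3f; flagged: %s\n",
              max(x$table$asmd_weighted),
              if (length(x$flags)) paste(x$flags, collapse = ", ")
              else "none"))
  cat("  propensity overlap quantiles:\n")
  print(round(x$overlap, 3))
  invisible(x)
}

#' Export a balance report
#'
#' @param report A `balance_report`.
#' @param path Output path; `.csv` writes the ASMD table, `.json` the full
#'   report.
#' @export
write_balance_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    writeLines(jsonlite::toJSON(
      list(table = report$table,
           overlap = as.data.frame(report$overlap),
           threshold = report$threshold, flags = report$flags),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE),
      path)
  } else {
    utils::write.csv(report$table, path, row.names = FALSE)
  }
  invisible(path)
}
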