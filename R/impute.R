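#' Control parameters for iterative random-forest imputation
#'
#' @param max_iterations Maximum sweeps over the variables (default 10).
#' @param num_trees Trees per forest (default 100).
#' @param seed Integer seed.
#' @return A list of class `impute_control`.
#' @export
impute_control <- function(max_iterations = 10L, num_trees = 100L,
                           seed = 1L) {
  stopifnot(max_iterations >= 1L)
  structure(list(max_iterations = as.integer(max_iterations),
                 num_trees = as.integer(num_trees), seed = as.integer(seed)),
            class = "impute_control")
}

#' Iterative random-forest imputation of a cohort
#'
#' missForest-style single imputation: missing numerics are initialized with
#' the observed mean and categoricals with the observed mode; variables are
#' then revisited in order of increasing missingness, each regressed on all
#' other variables with a random forest fit on its originally observed rows,
#' and its missing cells replaced by the forest predictions.  Sweeps continue
#' until the divergence criterion (normalized squared change over numeric
#' imputations plus disagreement fraction over categorical imputations)
#' first increases, or `max_iterations` is reached; the values from the
#' sweep before the increase are returned.  Observed cells are never
#' altered, and imputed numerics are clipped to their schema domains.
#'
#' @param cohort A `cohort`; every variable needs at least one observed
#'   value.
#' @param config An [impute_control()].
#' @return A fully observed `cohort` with `provenance = "imputed"` and the
#'   logical imputation mask attached as attribute `imputation_mask`.
#' @export
rf_impute <- function(cohort, config = impute_control()) {
  df <- as.data.frame(cohort)
  sch <- cohort_schema()
  vars <- setdiff(names(df), "patient_id")
  mask <- vapply(df[vars], is.na, logical(nrow(df)))
  if (nrow(df) == 1L) mask <- matrix(mask, nrow = 1L,
                                     dimnames = list(NULL, vars))
  if (!any(mask)) {
    out <- as_cohort(df, provenance = attr(cohort, "provenance") %||%
                       "observed")
    attr(out, "imputation_mask") <- mask
    return(out)
  }
  all_missing <- colSums(!mask) == 0L
  if (any(all_missing)) {
    stop("rf_impute: variable(s) with no observed values: ",
         paste(vars[all_missing], collapse = ", "), call. = FALSE)
  }

  mode_of <- function(x) names(which.max(table(x)))
  clip_domain <- function(v, x) {
    row <- sch[sch$column == v, ]
    if (nrow(row) == 1L && !is.na(row$min)) x <- clip(x, row$min, row$max)
    if (nrow(row) == 1L && row$type == "integer") x <- round(x)
    x
  }
  # mean / mode initialization
  for (v in vars) {
    na <- mask[, v]
    if (!any(na)) next
    if (is.numeric(df[[v]])) {
      df[[v]][na] <- clip_domain(v, mean(df[[v]][!na]))
    } else if (is.logical(df[[v]])) {
      df[[v]][na] <- as.logical(mode_of(df[[v]][!na]))
    } else {
      df[[v]][na] <- mode_of(df[[v]][!na])
    }
  }

  targets <- vars[colSums(mask) > 0L]
  targets <- targets[order(colSums(mask[, targets, drop = FALSE]))]
  prev <- df
  prev_div <- Inf
  for (iter in seq_len(config$max_iterations)) {
    old <- df
    for (v in targets) {
      na <- mask[, v]
      preds <- setdiff(vars, v)
      train <- df[!na, c(preds, v)]
      y_is_cat <- !is.numeric(df[[v]])
      if (y_is_cat) train[[v]] <- factor(train[[v]])
      fit <- ranger::ranger(
        stats::as.formula(paste0("`", v, "` ~ .")), data = train,
        num.trees = config$num_trees, seed = config$seed + iter,
        num.threads = 1, respect.unordered.factors = "order")
      pred <- stats::predict(fit, data = df[na, preds, drop = FALSE],
                             num.threads = 1)$predictions
      if (y_is_cat) {
        pred <- as.character(pred)
        if (is.logical(df[[v]])) pred <- as.logical(pred)
        df[[v]][na] <- pred
      } else {
        df[[v]][na] <- clip_domain(v, as.numeric(pred))
      }
    }
    # divergence between successive imputations (missForest convention)
    num_num <- 0; den_num <- 0; mism <- 0; n_cat <- 0
    for (v in targets) {
      na <- mask[, v]
      if (is.numeric(df[[v]])) {
        num_num <- num_num + sum((df[[v]][na] - old[[v]][na])^2)
        den_num <- den_num + sum(df[[v]][na]^2)
      } else {
        mism <- mism + sum(as.character(df[[v]][na]) !=
                             as.character(old[[v]][na]))
        n_cat <- n_cat + sum(na)
      }
    }
    div <- (if (den_num > 0) num_num / den_num else 0) +
      (if (n_cat > 0) mism / n_cat else 0)
    if (div >= prev_div) {
      df <- prev
      break
    }
    prev <- df
    prev_div <- div
  }
  out <- as_cohort(df, provenance = "imputed")
  attr(out, "imputation_mask") <- mask
  out
}

#' Write an imputed cohort with its sidecar mask
#'
#' @param cohort An imputed `cohort` from [rf_impute()].
#' @param path Cohort CSV path; the mask is written next to it with suffix
#'   `_mask.csv`.
#' @export
write_imputed <- function(cohort, path) {
  write_cohort(cohort, path)
  mask <- attr(cohort, "imputation_mask")
  mask_path <- sub("\\.csv$", "_mask.csv", path)
  utils::write.csv(
    cbind(data.frame(patient_id = cohort$patient_id), as.data.frame(mask)),
    mask_path, row.names = FALSE)
  invisible(c(path, mask_path))
}
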