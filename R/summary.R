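#' Descriptive summary of a cohort by treatment arm
#'
#' Builds the standard baseline/outcome summary table: for continuous
#' variables, mean (SD) \[range\] with a two-sided unpaired t test when the
#' pooled distribution is approximately normal, otherwise median (IQR)
#' \[range\] with a two-sided Wilcoxon rank-sum test; for categorical
#' variables, counts (column percentages) with an upper-tail Pearson chi-square
#' test without continuity correction.  Normality is decided by a fixed,
#' reproducible rule: absolute pooled sample skewness below 1.
#'
#' @param cohort A `cohort` data frame with both arms non-empty.
#' @param variables Columns to summarize; defaults to all candidate and
#'   confounder covariates plus the injured-hand and patient-reported outcome
#'   measures.
#' @return An object of class `cohort_summary`: a list with data frames
#'   `continuous` and `categorical` and the arm sizes.
#' @export
summarize_cohort <- function(cohort, variables = NULL) {
  A <- factor(cohort$treatment, levels = treatment_levels())
  if (any(table(A) == 0L)) {
    stop("summarize_cohort: both treatment arms must be non-empty",
         call. = FALSE)
  }
  if (is.null(variables)) {
    sch <- cohort_schema()
    variables <- c(sch$column[sch$role %in% c("candidate", "confounder")],
                   "grip_injured_kg", "pinch_lateral_inj_kg",
                   "pinch_2pt_inj_kg", "pinch_3pt_inj_kg", "nine_hole_inj_s",
                   "pain_inj_0_100", "mhq_0_100", "dash_0_100")
  }
  cont <- list(); catg <- list()
  fmt <- function(x) formatC(x, format = "fg", digits = 3)
  for (v in variables) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      ok <- !is.na(x)
      normal <- abs(sample_skewness(x)) < 1
      desc <- function(idx) {
        xi <- x[idx & ok]
        if (length(xi) == 0L) return(NA_character_)
        if (normal) {
          sprintf("%s (%s) [%s-%s]", fmt(mean(xi)), fmt(stats::sd(xi)),
                  fmt(min(xi)), fmt(max(xi)))
        } else {
          q <- stats::quantile(xi, c(0.25, 0.5, 0.75), names = FALSE)
          sprintf("%s (%s-%s) [%s-%s]", fmt(q[2]), fmt(q[1]), fmt(q[3]),
                  fmt(min(xi)), fmt(max(xi)))
        }
      }
      p <- tryCatch({
        if (normal) {
          stats::t.test(x[A == "revision_amputation"],
                        x[A == "replantation"])$p.value
        } else {
          stats::wilcox.test(x[A == "revision_amputation"],
                             x[A == "replantation"], exact = FALSE)$p.value
        }
      }, error = function(e) NA_real_)
      cont[[v]] <- data.frame(
        variable = v, display = if (normal) "mean_sd" else "median_iqr",
        overall = desc(rep(TRUE, length(x))),
        revision_amputation = desc(A == "revision_amputation"),
        replantation = desc(A == "replantation"),
        test = if (normal) "t" else "wilcoxon", p_value = p)
    } else {
      xf <- if (is.logical(x)) factor(ifelse(x, "yes", "no"),
                                      levels = c("yes", "no")) else factor(x)
      observed <- droplevels(xf[!is.na(xf)])
      if (nlevels(observed) < 2L) {
        warning(sprintf("summarize_cohort: '%s' has a single observed level; ",
                        v), "test omitted", call. = FALSE)
        p <- NA_real_
      } else {
        tab <- table(droplevels(xf), A)
        # upper-tail Pearson chi-square, no continuity correction
        p <- suppressWarnings(
          stats::chisq.test(tab, correct = FALSE)$p.value)
      }
      cnt <- function(lv, idx) {
        n <- sum(xf[idx] == lv, na.rm = TRUE)
        d <- sum(!is.na(xf[idx]))
        sprintf("%d (%d)", n, if (d > 0) round(100 * n / d) else 0)
      }
      for (lv in levels(droplevels(xf))) {
        catg[[paste(v, lv, sep = ":")]] <- data.frame(
          variable = v, level = lv,
          overall = cnt(lv, rep(TRUE, length(xf))),
          revision_amputation = cnt(lv, A == "revision_amputation"),
          replantation = cnt(lv, A == "replantation"),
          n_overall = sum(xf == lv, na.rm = TRUE),
          test = "chisq", p_value = p)
      }
    }
  }
  structure(list(
    continuous = do.call(rbind, c(cont, list(make.row.names = FALSE))),
    categorical = do.call(rbind, c(catg, list(make.row.names = FALSE))),
    n = c(overall = length(A),
          revision_amputation = sum(A == "revision_amputation"),
          replantation = sum(A == "replantation"))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: N = %d (revision amputation %d, replantation %d)\n\n",
              x$n[["overall"]], x$n[["revision_amputation"]],
              x$n[["replantation"]]))
  if (!is.null(x$continuous) && nrow(x$continuous)) {
    cat("Continuous variables:\n")
    print(x$continuous, row.names = FALSE)
  }
  if (!is.null(x$categorical) && nrow(x$categorical)) {
    cat("\nCategorical variables:\n")
    print(x$categorical[, setdiff(names(x$categorical), "n_overall")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Export a cohort summary as JSON
#'
#' @param summary A `cohort_summary`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
summary_json <- function(summary, path = NULL) {
  out <- jsonlite::toJSON(unclass(summary), dataframe = "rows",
                          auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}
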