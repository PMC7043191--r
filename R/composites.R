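#' Standardize a vector to z-scores
#'
#' Centers and scales by the sample standard deviation (denominator n - 1).
#' A constant vector is a degenerate measure and raises an error rather than
#' silently producing `NaN`.
#'
#' @param values Numeric vector, length >= 2, no missing values.
#' @param measure Name used in error messages.
#' @return Numeric vector with sample mean 0 and sample SD 1.
#' @export
standardize <- function(values, measure = "measure") {
  if (anyNA(values)) {
    stop(sprintf("standardize: missing values in '%s'", measure),
         call. = FALSE)
  }
  if (length(values) < 2L) {
    stop(sprintf("standardize: '%s' needs at least 2 observations", measure),
         call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop(sprintf("standardize: '%s' has zero variance", measure),
         call. = FALSE)
  }
  (values - mean(values)) / s
}

new_composite <- function(name, scores, component_log, patient_id) {
  structure(list(name = name, scores = scores,
                 component_log = component_log, patient_id = patient_id),
            class = "composite_outcome")
}

require_fields <- function(cohort, fields, what) {
  miss <- vapply(cohort[fields], anyNA, logical(1))
  if (any(miss)) {
    stop(sprintf("%s: missing values in %s; restrict to complete cases first",
                 what, paste(fields[miss], collapse = ", ")), call. = FALSE)
  }
}

#' Composite hand-strength outcome
#'
#' For each of grip, lateral pinch, 2-point pinch and 3-point pinch the
#' injured-minus-healthy difference is formed, each difference is
#' standardized over the analysis cohort, and the composite is the mean of
#' the four z-scores.  Larger values mean the injured hand recovered to (or
#' above) the healthy hand.
#'
#' @param cohort A `cohort` with all eight strength fields observed.
#' @return A `composite_outcome` with per-measure differences retained in
#'   `component_log`.
#' @export
strength_composite <- function(cohort) {
  require_fields(cohort, outcome_fields("strength"), "strength_composite")
  pairs <- list(
    grip = c("grip_injured_kg", "grip_healthy_kg"),
    pinch_lateral = c("pinch_lateral_inj_kg", "pinch_lateral_hea_kg"),
    pinch_2pt = c("pinch_2pt_inj_kg", "pinch_2pt_hea_kg"),
    pinch_3pt = c("pinch_3pt_inj_kg", "pinch_3pt_hea_kg"))
  log <- data.frame(patient_id = cohort$patient_id)
  zs <- matrix(NA_real_, nrow(cohort), length(pairs),
               dimnames = list(NULL, names(pairs)))
  for (m in names(pairs)) {
    d <- cohort[[pairs[[m]][1]]] - cohort[[pairs[[m]][2]]]
    log[[paste0("d_", m)]] <- d
    zs[, m] <- standardize(d, m)
    log[[paste0("z_", m)]] <- zs[, m]
  }
  new_composite("strength", rowMeans(zs), log, cohort$patient_id)
}

#' Dexterity outcome from the 9-hole peg test
#'
#' Standardized healthy-minus-injured time difference: a slower injured hand
#' gives a negative difference, so larger values are preferred.
#'
#' @param cohort A `cohort` with both peg-test times observed (> 0 seconds).
#' @return A `composite_outcome`.
#' @export
dexterity_score <- function(cohort) {
  require_fields(cohort, outcome_fields("dexterity"), "dexterity_score")
  if (any(cohort$nine_hole_inj_s <= 0 | cohort$nine_hole_hea_s <= 0)) {
    stop("dexterity_score: peg-test times must be positive", call. = FALSE)
  }
  d <- cohort$nine_hole_hea_s - cohort$nine_hole_inj_s
  z <- standardize(d, "nine_hole")
  new_composite("dexterity", z,
                data.frame(patient_id = cohort$patient_id, d_nine_hole = d,
                           z_nine_hole = z),
                cohort$patient_id)
}

#' Pain outcome
#'
#' Standardized healthy-minus-injured pain difference on the 0-100 scale
#' (larger pain values are worse, so a less painful injured hand scores
#' higher).  The construct assumes healthy-hand pain does not exceed
#' injured-hand pain; records violating it are handled per
#' `violation`: truncated to a zero difference (default, preserving sample
#' size) or dropped.  Either way the violations are flagged in
#' `component_log$violated`.
#'
#' @param cohort A `cohort` with both pain fields observed, in \[0, 100\].
#' @param violation `"truncate"` or `"drop"`.
#' @return A `composite_outcome`.
#' @export
pain_score <- function(cohort, violation = c("truncate", "drop")) {
  violation <- match.arg(violation)
  require_fields(cohort, outcome_fields("pain"), "pain_score")
  d <- cohort$pain_hea_0_100 - cohort$pain_inj_0_100
  violated <- d > 0
  id <- cohort$patient_id
  if (violation == "truncate") {
    d[violated] <- 0
  } else {
    d <- d[!violated]
    id <- id[!violated]
  }
  z <- standardize(d, "pain")
  new_composite("pain", z,
                data.frame(patient_id = id, d_pain = d, z_pain = z,
                           violated = if (violation == "truncate") violated
                           else violated[!violated]),
                id)
}

#' Patient-reported quality-of-life outcome
#'
#' Mean of standardized MHQ and standardized reversed DASH (100 - DASH), so
#' that larger is better for both components.
#'
#' @param cohort A `cohort` with MHQ and DASH observed, in \[0, 100\].
#' @return A `composite_outcome`.
#' @export
qol_score <- function(cohort) {
  require_fields(cohort, outcome_fields("qol"), "qol_score")
  z_mhq <- standardize(cohort$mhq_0_100, "mhq")
  z_rdash <- standardize(100 - cohort$dash_0_100, "reverse_dash")
  new_composite("qol", (z_mhq + z_rdash) / 2,
                data.frame(patient_id = cohort$patient_id, z_mhq = z_mhq,
                           z_reverse_dash = z_rdash),
                cohort$patient_id)
}

#' Build one of the four composite outcomes
#'
#' @param cohort A `cohort`, complete for the outcome's fields.
#' @param outcome `"strength"`, `"dexterity"`, `"pain"` or `"qol"`.
#' @param ... Passed to the outcome-specific constructor (e.g. `violation`
#'   for `"pain"`).
#' @return A `composite_outcome`.
#' @export
composite_outcome <- function(cohort, outcome = c("strength", "dexterity",
                                                  "pain", "qol"), ...) {
  outcome <- match.arg(outcome)
  switch(outcome,
         strength = strength_composite(cohort),
         dexterity = dexterity_score(cohort),
         pain = pain_score(cohort, ...),
         qol = qol_score(cohort))
}

#' @export
print.composite_outcome <- function(x, ...) {
  cat(sprintf("<composite_outcome> %s: %d patients, mean %.3g, sd %.3g\n",
              x$name, length(x$scores), mean(x$scores),
              stats::sd(x$scores)))
  invisible(x)
}

#' Export composite scores with their component log
#'
#' @param composite A `composite_outcome`.
#' @param path Output CSV path.
#' @export
write_composite <- function(composite, path) {
  out <- cbind(composite$component_log,
               score = composite$scores)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
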