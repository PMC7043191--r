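#' Cohort schema for finger-amputation outcome analyses
#'
#' One row per patient, wide layout.  Covariates follow the candidate and
#' confounder sets used for estimating treatment decision rules; raw outcome
#' measures are bilateral (injured and healthy hand) so that recovery-type
#' composites can be formed.  Missing cells are `NA` everywhere; readers never
#' impute.
#'
#' @return A data frame with one row per column of the cohort table:
#'   `column`, `type` (`"numeric"`, `"integer"`, `"logical"`, `"factor"`,
#'   `"character"`), `role` (`"id"`, `"candidate"`, `"confounder"`,
#'   `"treatment"`, `"outcome"`), `levels` (comma-separated for factors),
#'   `min`, `max` (for bounded numerics).
#' @export
cohort_schema <- function() {
  fac <- function(...) paste(c(...), collapse = ",")
  rbind(
    data.frame(column = "patient_id", type = "character", role = "id",
               levels = "", min = NA_real_, max = NA_real_),
    data.frame(column = "age", type = "numeric", role = "candidate",
               levels = "", min = 18, max = 120),
    data.frame(column = "sex", type = "factor", role = "confounder",
               levels = fac("male", "female"), min = NA, max = NA),
    data.frame(column = "site", type = "factor", role = "confounder",
               levels = fac("US", "Asia"), min = NA, max = NA),
    data.frame(column = "race_ethnicity", type = "factor", role = "confounder",
               levels = fac("asian", "white", "black", "hispanic", "other"),
               min = NA, max = NA),
    data.frame(column = "education", type = "factor", role = "confounder",
               levels = fac("high_school_or_less", "some_college",
                            "college_graduate"), min = NA, max = NA),
    data.frame(column = "income", type = "factor", role = "confounder",
               levels = fac("low", "middle", "high"), min = NA, max = NA),
    data.frame(column = "marital", type = "factor", role = "confounder",
               levels = fac("married", "single", "other"), min = NA, max = NA),
    data.frame(column = "employment", type = "factor", role = "confounder",
               levels = fac("employed", "unemployed", "retired", "other"),
               min = NA, max = NA),
    data.frame(column = "occupation_group", type = "factor",
               role = "confounder",
               levels = fac("manual", "non_manual", "not_working"),
               min = NA, max = NA),
    data.frame(column = "insurance", type = "factor", role = "confounder",
               levels = fac("yes", "no"), min = NA, max = NA),
    data.frame(column = "insurance_type", type = "factor", role = "confounder",
               levels = fac("public", "private", "none"), min = NA, max = NA),
    data.frame(column = "work_related", type = "logical", role = "confounder",
               levels = "", min = NA, max = NA),
    data.frame(column = "n_fingers_amputated", type = "integer",
               role = "candidate", levels = "", min = 1, max = 5),
    data.frame(column = "thumb_amputated", type = "logical",
               role = "candidate", levels = "", min = NA, max = NA),
    data.frame(column = "dominant_hand_injured", type = "logical",
               role = "candidate", levels = "", min = NA, max = NA),
    data.frame(column = "mechanism", type = "factor", role = "candidate",
               levels = fac("clean_cut", "avulsion", "crush"),
               min = NA, max = NA),
    data.frame(column = "amputation_level", type = "factor",
               role = "candidate", levels = fac("distal", "proximal"),
               min = NA, max = NA),
    data.frame(column = "bilateral", type = "logical", role = "candidate",
               levels = "", min = NA, max = NA),
    data.frame(column = "treatment", type = "factor", role = "treatment",
               levels = fac("revision_amputation", "replantation"),
               min = NA, max = NA),
    data.frame(column = c("grip_injured_kg", "grip_healthy_kg"),
               type = "numeric", role = "outcome", levels = "",
               min = 0, max = 120),
    data.frame(column = c("pinch_lateral_inj_kg", "pinch_lateral_hea_kg",
                          "pinch_2pt_inj_kg", "pinch_2pt_hea_kg",
                          "pinch_3pt_inj_kg", "pinch_3pt_hea_kg"),
               type = "numeric", role = "outcome", levels = "",
               min = 0, max = 60),
    data.frame(column = c("nine_hole_inj_s", "nine_hole_hea_s"),
               type = "numeric", role = "outcome", levels = "",
               min = 0, max = 600),
    data.frame(column = c("pain_inj_0_100", "pain_hea_0_100",
                          "mhq_0_100", "dash_0_100"),
               type = "numeric", role = "outcome", levels = "",
               min = 0, max = 100)
  )
}

#' Treatment arm labels
#'
#' Exactly two arms; `replantation` is the reference arm for the propensity
#' score P(A = replantation | X).
#' @export
treatment_levels <- function() c("revision_amputation", "replantation")

schema_levels <- function(schema_row) {
  strsplit(schema_row$levels, ",", fixed = TRUE)[[1]]
}

#' Raw outcome fields required to build one composite outcome
#'
#' @param outcome One of `"strength"`, `"dexterity"`, `"pain"`, `"qol"`, or
#'   `"all"` for the union.
#' @return Character vector of cohort column names.
#' @export
outcome_fields <- function(outcome = c("strength", "dexterity", "pain",
                                       "qol", "all")) {
  outcome <- match.arg(outcome)
  fields <- list(
    strength = c("grip_injured_kg", "grip_healthy_kg",
                 "pinch_lateral_inj_kg", "pinch_lateral_hea_kg",
                 "pinch_2pt_inj_kg", "pinch_2pt_hea_kg",
                 "pinch_3pt_inj_kg", "pinch_3pt_hea_kg"),
    dexterity = c("nine_hole_inj_s", "nine_hole_hea_s"),
    pain = c("pain_inj_0_100", "pain_hea_0_100"),
    qol = c("mhq_0_100", "dash_0_100")
  )
  if (outcome == "all") unname(unlist(fields)) else fields[[outcome]]
}

#' Candidate tailoring covariates for each analysis
#'
#' The primary analysis tailors on injury characteristics and age; sensitivity
#' analysis 1 collapses injury characteristics to a single ordinal severity
#' group; sensitivity analysis 2 drops age; sensitivity analysis 3 uses the
#' primary candidates on the imputed full cohort.
#'
#' @param analysis One of `"primary"`, `"sens1"`, `"sens2"`, `"sens3"`.
#' @return Character vector of covariate names (for `"sens1"`, the derived
#'   column `injury_group`).
#' @export
candidate_covariates <- function(analysis = c("primary", "sens1", "sens2",
                                              "sens3")) {
  analysis <- match.arg(analysis)
  primary <- c("n_fingers_amputated", "thumb_amputated",
               "dominant_hand_injured", "mechanism", "amputation_level",
               "bilateral", "age")
  switch(analysis,
         primary = primary,
         sens1 = "injury_group",
         sens2 = setdiff(primary, "age"),
         sens3 = primary)
}

#' Confounders entering the propensity model
#'
#' All measured baseline covariates (candidates plus demographic and
#' socio-economic confounders); no a priori covariate selection.
#' @return Character vector of covariate names.
#' @export
propensity_covariates <- function() {
  sch <- cohort_schema()
  sch$column[sch$role %in% c("candidate", "confounder")]
}

validate_cohort_frame <- function(df, context = "cohort") {
  sch <- cohort_schema()
  unknown <- setdiff(names(df), sch$column)
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown column(s): %s", context,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing_cols <- setdiff(sch$column, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing column(s): %s", context,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (i in seq_len(nrow(sch))) {
    cn <- sch$column[i]
    x <- df[[cn]]
    if (sch$type[i] == "factor") {
      lev <- schema_levels(sch[i, ])
      bad <- !is.na(x) & !(as.character(x) %in% lev)
      if (any(bad)) {
        stop(sprintf("%s: column '%s' has invalid level(s) %s (rows %s)",
                     context, cn,
                     paste(unique(as.character(x)[bad]), collapse = ", "),
                     paste(utils::head(which(bad), 5), collapse = ", ")),
             call. = FALSE)
      }
      df[[cn]] <- factor(as.character(x), levels = lev)
    } else if (sch$type[i] %in% c("numeric", "integer")) {
      x <- as.numeric(x)
      if (!is.na(sch$min[i])) {
        # peg-test times must be strictly positive; other bounds are closed
        strict <- cn %in% c("nine_hole_inj_s", "nine_hole_hea_s")
        lo_bad <- if (strict) x <= sch$min[i] else x < sch$min[i]
        hi_bad <- if (is.na(sch$max[i])) FALSE else x > sch$max[i]
        bad <- !is.na(x) & (lo_bad | hi_bad)
        if (any(bad)) {
          stop(sprintf(
            "%s: column '%s' out of range [%s, %s] at row(s) %s (id %s)",
            context, cn, sch$min[i], sch$max[i],
            paste(utils::head(which(bad), 5), collapse = ", "),
            paste(utils::head(df$patient_id[bad], 5), collapse = ", ")),
            call. = FALSE)
        }
      }
      df[[cn]] <- if (sch$type[i] == "integer") {
        ifelse(is.na(x), NA_integer_, as.integer(round(x)))
      } else x
    } else if (sch$type[i] == "logical") {
      if (!is.logical(x)) {
        xl <- tolower(as.character(x))
        conv <- ifelse(is.na(x), NA,
                       xl %in% c("true", "t", "1", "yes"))
        bad <- !is.na(x) & !(xl %in% c("true", "t", "1", "yes", "false",
                                       "f", "0", "no"))
        if (any(bad)) {
          stop(sprintf("%s: column '%s' not interpretable as logical (rows %s)",
                       context, cn,
                       paste(utils::head(which(bad), 5), collapse = ", ")),
               call. = FALSE)
        }
        df[[cn]] <- conv
      }
    } else {
      df[[cn]] <- as.character(x)
    }
  }
  if (anyDuplicated(df$patient_id)) {
    stop(sprintf("%s: duplicated patient_id", context), call. = FALSE)
  }
  df[, sch$column]
}

#' Construct a cohort object from a data frame
#'
#' Validates column names, types, categorical levels and numeric ranges
#' against [cohort_schema()]; missing values stay `NA`.
#'
#' @param df Data frame in the cohort schema.
#' @param provenance `"observed"`, `"synthetic"`, or `"imputed"`.
#' @return A data frame of class `cohort`.
#' @export
as_cohort <- function(df, provenance = c("observed", "synthetic", "imputed")) {
  provenance <- match.arg(provenance)
  df <- validate_cohort_frame(as.data.frame(df))
  structure(df, class = c("cohort", "data.frame"), provenance = provenance)
}

#' Read a cohort CSV
#'
#' UTF-8 CSV with header row, one row per patient, missing cells empty or
#' `NA`.  Unknown columns, invalid levels, and out-of-range values raise
#' errors naming the offending column and row.
#'
#' @param path Path to the CSV file.
#' @param provenance Provenance tag for the resulting cohort.
#' @return A `cohort` data frame.
#' @export
read_cohort <- function(path, provenance = "observed") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  as_cohort(df, provenance = provenance)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' `x` field for field.
#'
#' @param cohort A `cohort` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict a cohort to complete cases
#'
#' Drops records with any missing value among `required_fields` (default:
#' every candidate covariate plus every raw outcome measure), preserving row
#' order.  The counts removed per field are attached as attribute
#' `removed_per_field` for audit.
#'
#' @param cohort A `cohort` data frame.
#' @param required_fields Character vector of schema fields that must be
#'   observed.
#' @return The complete-case `cohort`; errors if a treatment arm empties.
#' @export
complete_cases <- function(cohort,
                           required_fields = c(candidate_covariates("primary"),
                                               outcome_fields("all"))) {
  bad <- setdiff(required_fields, names(cohort))
  if (length(bad) > 0) {
    stop("required_fields not in schema: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  miss <- vapply(cohort[required_fields], function(x) is.na(x),
                 logical(nrow(cohort)))
  if (nrow(cohort) == 1L) miss <- matrix(miss, nrow = 1L)
  keep <- rowSums(miss) == 0
  removed <- colSums(miss[!keep, , drop = FALSE])
  out <- cohort[keep, , drop = FALSE]
  arms <- table(factor(out$treatment, levels = treatment_levels()))
  if (nrow(out) == 0L || any(arms == 0L)) {
    stop("complete_cases: a treatment arm is empty after filtering",
         call. = FALSE)
  }
  attr(out, "removed_per_field") <- removed
  attr(out, "provenance") <- attr(cohort, "provenance")
  class(out) <- class(cohort)
  out
}

#' Derive the ordinal injury-severity group
#'
#' Deterministic 8-level ordinal coding of amputation severity from the
#' number of fingers amputated, thumb involvement, and amputation level
#' relative to the PIP/IP joint:
#' 1. single finger (excluding thumb), distal to the PIP joint
#' 2. single finger (excluding thumb), proximal to the PIP joint
#' 3. thumb only, distal to the IP joint
#' 4. thumb only, proximal to the IP joint
#' 5. 2 fingers amputated (excluding thumb)
#' 6. 3 or more fingers amputated (excluding thumb)
#' 7. 2 fingers amputated (including thumb)
#' 8. 3 or more fingers amputated (including thumb)
#'
#' @param cohort A `cohort` data frame (or any data frame with columns
#'   `n_fingers_amputated`, `thumb_amputated`, `amputation_level`).
#' @return Integer vector of levels 1-8, one per record.
#' @export
derive_injury_group <- function(cohort) {
  n <- cohort$n_fingers_amputated
  thumb <- cohort$thumb_amputated
  distal <- cohort$amputation_level == "distal"
  if (any(is.na(n) | is.na(thumb) | is.na(distal))) {
    stop("derive_injury_group: n_fingers_amputated, thumb_amputated and ",
         "amputation_level must be observed", call. = FALSE)
  }
  ifelse(n == 1L,
         ifelse(thumb, ifelse(distal, 3L, 4L), ifelse(distal, 1L, 2L)),
         ifelse(n == 2L, ifelse(thumb, 7L, 5L), ifelse(thumb, 8L, 6L)))
}

#' @export
print.cohort <- function(x, ...) {
  arms <- table(factor(x$treatment, levels = treatment_levels()))
  cat(sprintf("<cohort> %d patients (%s), %d revision amputation / %d replantation\n",
              nrow(x), attr(x, "provenance") %||% "observed",
              arms[["revision_amputation"]], arms[["replantation"]]))
  n_miss <- sum(is.na(as.data.frame(x)))
  cat(sprintf("  missing cells: %d\n", n_miss))
  invisible(x)
}
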